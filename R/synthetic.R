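#' Configuration for the synthetic food web generator
#'
#' Defaults emulate the diversity of published Ecopath models of marine
#' systems: webs of 6-68 functional groups (26 on average), lognormal
#' biomasses spanning several orders of magnitude, production and
#' consumption rates declining log-linearly with trophic height, an
#' optional detritus pool with detritivory (switching recycling on), and
#' catches on a subset of consumer groups.
#'
#' @param n_groups Total number of groups including detritus.
#' @param n_producers Number of pure primary producers (>= 1).
#' @param include_detritus Add a detritus pool fed by egestion and
#'   non-predation mortality (default `TRUE`).
#' @param connectance Probability that an eligible (trophically lower)
#'   prey enters a consumer's diet; controls link density.
#' @param detritivory Probability that a consumer also feeds on detritus.
#' @param b_median,b_sigma Median and log-sd of the biomass lognormal.
#' @param b_decline Exponential decline of biomass with normalized
#'   trophic rank (top predators are rarer).
#' @param pb_producer Median P/B of producers, y-1.
#' @param pb_base,pb_top Consumer P/B declines log-linearly from
#'   `pb_base` (lowest consumers) to `pb_top` (apex), y-1.
#' @param ge_range Range of gross food-conversion efficiency P/Q used to
#'   set QB = PB / GE.
#' @param catch_fraction Fraction of consumer groups carrying catches.
#' @param catch_intensity Fishing rate relative to production: Y =
#'   intensity * B * PB * U(0.2, 1).
#' @param ee_cap Balance target: predator biomasses are rescaled until all
#'   EE <= `ee_cap`.
#' @param seed Optional integer; the same seed yields an identical web.
#' @return A `web_config` list.
#' @export
web_config <- function(n_groups = 26, n_producers = 2, include_detritus = TRUE,
                       connectance = 0.25, detritivory = 0.4,
                       b_median = 1, b_sigma = 1, b_decline = 2.5,
                       pb_producer = 40, pb_base = 12, pb_top = 0.4,
                       ge_range = c(0.1, 0.3),
                       catch_fraction = 0.3, catch_intensity = 0.1,
                       ee_cap = 0.95, seed = NULL) {
  stopifnot(n_producers >= 1,
            n_groups >= n_producers + 1 + include_detritus,
            connectance > 0, connectance < 1,
            ee_cap > 0, ee_cap <= 1)
  structure(as.list(environment()), class = "web_config")
}

#' Generate a balanced synthetic food web
#'
#' Draws a trophically ordered web: consumers feed only on lower-ranked
#' groups (plus, optionally, detritus), so trophic levels are always
#' solvable and the diet graph is acyclic apart from the detritus loop.
#' Diet proportions are Dirichlet-distributed per predator. Biomasses,
#' rates and catches are drawn as configured; the web is then balanced by
#' iteratively rescaling the biomass (and catch) of predators of any
#' overloaded prey until every ecotrophic efficiency is at or below
#' `ee_cap`. Deterministic under `config$seed`.
#'
#' @param config A [web_config()].
#' @return A balanced `food_web_model` (EE estimated and stored).
#' @export
#' @examples
#' w <- generate_web(web_config(n_groups = 12, seed = 1))
#' max(w$groups$EE[w$groups$role != "detritus"])
generate_web <- function(config = web_config()) {
  stopifnot(inherits(config, "web_config"))
  cf <- config
  if (!is.null(cf$seed)) set.seed(cf$seed)
  nd <- as.integer(cf$include_detritus)
  n <- cf$n_groups
  nl <- n - nd
  np <- cf$n_producers
  nc <- nl - np
  if (nc < 1) stop("infeasible configuration: no consumers")

  role <- c(rep("producer", np), rep("consumer", nc),
            if (nd) "detritus")
  name <- c(sprintf("prod%02d", seq_len(np)), sprintf("cons%02d", seq_len(nc)),
            if (nd) "detritus")
  rank <- c(rep(0, np), seq_len(nc) / nc, if (nd) 0)  # normalized trophic order

  diet <- matrix(0, n, n, dimnames = list(name, name))
  det_idx <- if (nd) n else integer(0)
  for (j in seq_len(nc)) {
    col <- np + j
    eligible <- seq_len(np + j - 1)                       # strictly lower-ranked
    k <- max(1L, stats::rbinom(1, length(eligible), cf$connectance))
    prey <- if (length(eligible) == 1) eligible else
      sample(eligible, min(k, length(eligible)))
    if (nd && stats::runif(1) < cf$detritivory) prey <- c(prey, det_idx)
    w <- stats::rgamma(length(prey), 1)
    diet[prey, col] <- w / sum(w)
  }

  B <- cf$b_median * exp(stats::rnorm(n, 0, cf$b_sigma) - cf$b_decline * rank)
  PB <- numeric(n)
  PB[seq_len(np)] <- cf$pb_producer * exp(stats::rnorm(np, 0, 0.3))
  PB[np + seq_len(nc)] <- cf$pb_base * (cf$pb_top / cf$pb_base)^rank[np + seq_len(nc)] *
    exp(stats::rnorm(nc, 0, 0.2))
  ge <- stats::runif(n, cf$ge_range[1], cf$ge_range[2])
  QB <- ifelse(role == "consumer", PB / ge, NA_real_)
  if (nd) { B[n] <- cf$b_median * 5; PB[n] <- 0 }

  Y <- numeric(n)
  fished <- which(role == "consumer")
  nf <- round(cf$catch_fraction * length(fished))
  if (nf > 0 && cf$catch_intensity > 0) {
    target <- sample(fished, nf)
    Y[target] <- cf$catch_intensity * B[target] * PB[target] *
      stats::runif(nf, 0.2, 1)
  }

  groups <- data.frame(name = name, role = role, B = B, PB = PB, QB = QB,
                       Y = Y, stringsAsFactors = FALSE)
  m <- food_web_model(groups, diet, name = sprintf("synthetic web"))
  m <- balance_by_rescaling(m, cf$ee_cap)
  validate_model(m)
  m
}

# rescale predator biomasses (and their catches) until all EE <= cap
balance_by_rescaling <- function(m, cap = 0.95, max_iter = 500L) {
  for (it in seq_len(max_iter)) {
    ee <- c(estimate_ee(m))
    over <- which(ee > cap)
    if (!length(over)) {
      m$groups$EE <- as.numeric(ee)
      return(m)
    }
    g <- m$groups
    flows <- predation_flows(m)
    scale <- rep(1, nrow(g))
    for (i in over) {
      pred_i <- sum(flows[i, ])
      if (pred_i <= 0) {            # overload from catch/export alone
        m$groups$Y[i] <- 0.5 * cap * g$B[i] * g$PB[i]
        next
      }
      cap_i <- if (is_living(m)[i]) cap * g$B[i] * g$PB[i] else
        cap * detritus_inflow(m, ee)[i]
      avail <- cap_i - g$Y[i] - g$E[i] - g$BA[i]
      if (avail <= 0) {
        m$groups$Y[i] <- 0.5 * cap_i
        avail <- cap_i - m$groups$Y[i]
      }
      s_i <- max(min(0.95 * avail / pred_i, 1), 1e-6)
      preds <- which(flows[i, ] > 0)
      scale[preds] <- pmin(scale[preds], s_i)
    }
    m$groups$B <- m$groups$B * scale
    m$groups$Y <- m$groups$Y * scale
  }
  stop("balance not achieved within ", max_iter, " iterations")
}

#' Trait vocabularies for model collections
#'
#' The categorical classes used to label models in collection-level
#' analyses: ecosystem type (7), latitude band (4), ocean basin (7),
#' depth class (7), surface-area class (6), time period (4) and
#' exploitation state (3).
#'
#' @return Named list of character vectors.
#' @export
trait_vocabularies <- function() {
  list(
    ecosystem_type = c("lagoon", "estuary", "bay", "coastal", "reef",
                       "continental shelf", "upper slope"),
    latitude = c("0-15", "15-30", "30-60", "60-90"),
    basin = c("West Atlantic", "East Atlantic", "North and Baltic",
              "Mediterranean", "Indian", "West Pacific", "East Pacific"),
    depth = c("<5", "<10", "<20", "<50", "<100", "<200", ">200"),
    size = c("1-10", "10-100", "100-1000", "1000-10000", "10000-100000",
             ">100000"),
    period = c("<1970", "1970-1980", "1980-1990", ">1990"),
    exploitation = c("high", "low", "none")
  )
}

#' Generate a trait-labelled collection of balanced webs
#'
#' Stands in for a database of published models: draws `n_models` webs of
#' varying size, assigns each a random trait profile from
#' [trait_vocabularies()], and optionally injects known trait effects as
#' multiplicative shifts on generator parameters, so that recovery and
#' power of the collection-level statistics can be tested against a known
#' truth.
#'
#' @param n_models Number of webs (default 105).
#' @param config Base [web_config()]; `n_groups` is redrawn per model
#'   between `size_range[1]` and `size_range[2]`.
#' @param trait_effects Named list: `trait_effects$basin$"East Pacific"`
#'   is a named numeric vector of multipliers applied to `config` fields
#'   (e.g. `c(pb_producer = 3)`) for models carrying that level.
#' @param size_range Range of web sizes (default `c(6, 68)`).
#' @param traits Optional data frame of trait assignments (one row per
#'   model, columns from [trait_vocabularies()]); drawn at random when
#'   missing. Supplying them gives balanced designs for power studies.
#' @param seed Integer seed for the whole collection.
#' @return List with `models` (named list of `food_web_model`) and
#'   `traits` (data frame of trait classes plus covariates `n_groups`,
#'   `n_living`, `n_links`).
#' @export
generate_collection <- function(n_models = 105, config = web_config(),
                                trait_effects = list(),
                                size_range = c(6, 68), traits = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vocab <- trait_vocabularies()
  if (is.null(traits)) {
    traits <- as.data.frame(lapply(vocab, function(v)
      sample(v, n_models, replace = TRUE)), stringsAsFactors = FALSE)
  } else {
    traits <- as.data.frame(traits, stringsAsFactors = FALSE)
    stopifnot(nrow(traits) == n_models)
    check_trait_vocab(traits)
  }
  sizes <- pmin(pmax(round(stats::rlnorm(n_models, log(26), 0.35)),
                     size_range[1]), size_range[2])
  model_seeds <- sample.int(.Machine$integer.max, n_models)
  models <- vector("list", n_models)
  for (i in seq_len(n_models)) {
    cf <- config
    cf$n_groups <- sizes[i]
    cf$n_producers <- min(cf$n_producers, max(1, sizes[i] - 2))
    cf$seed <- model_seeds[i]
    for (trait in names(trait_effects)) {
      lev <- traits[[trait]][i]
      mult <- trait_effects[[trait]][[lev]]
      for (fld in names(mult)) cf[[fld]] <- cf[[fld]] * mult[[fld]]
    }
    models[[i]] <- generate_web(cf)
    models[[i]]$meta$name <- sprintf("web%03d", i)
  }
  names(models) <- sprintf("web%03d", seq_len(n_models))
  traits$n_groups <- vapply(models, function(m) nrow(m$groups), 0)
  traits$n_living <- vapply(models, function(m) sum(is_living(m)), 0)
  traits$n_links <- vapply(models, function(m) sum(m$diet > 0), 0)
  rownames(traits) <- names(models)
  list(models = models, traits = traits)
}

#' Four-group chain fixture
#'
#' A hand-balanced producer-herbivore-carnivore chain with a detritus
#' pool, used throughout the tests: EE = (0.2, 0.25, 0.5), TL =
#' (1, 2, 3, 1), mean transfer efficiency 5%, PPRc = 2.5, FCI = 0.
#'
#' @return A `food_web_model` with groups P, H, C, D.
#' @export
fixture_chain3 <- function() {
  groups <- data.frame(
    name = c("P", "H", "C", "D"),
    role = c("producer", "consumer", "consumer", "detritus"),
    B = c(10, 1, 0.1, 10),
    PB = c(10, 2, 1, 0),
    QB = c(NA, 20, 5, NA),
    Y = c(0, 0, 0.05, 0)
  )
  diet <- matrix(0, 4, 4)
  diet[1, 2] <- 1   # H eats P
  diet[2, 3] <- 1   # C eats H
  food_web_model(groups, diet, name = "chain3")
}
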