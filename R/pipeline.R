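#' Compute the full indicator set of a model
#'
#' Runs the whole per-model pipeline: mass balance, flow network,
#' throughput components, information and cycling indices, trophic and
#' omnivory indicators, Lindeman transfer efficiencies and fishing
#' indicators. Fishing indicators are `NA` (not zero) in unfished models,
#' as they are undefined rather than null there.
#'
#' @param m A `food_web_model`.
#' @param calibration P_sust calibration, see [psust_calibration()].
#' @return One-row data frame with columns `TST`, `PP_TST`, `FD_TST`,
#'   `Q_TST`, `R_TST`, `Ex_TST`, `PP_P`, `meanPz`, `maxPz`, `meanEE`,
#'   `TBco`, `TB_TST`, `mTLco`, `TEm`, `A_C`, `O_C`, `IFO`, `FCI`, `SOI`,
#'   `TC`, `TLc`, `PPR_pct`, `L_index`, `P_sust`.
#' @export
#' @examples
#' round(compute_indicators(fixture_chain3())$TEm, 2)  # 5
compute_indicators <- function(m, calibration = psust_calibration()) {
  m <- balance(m, warn = FALSE)
  net <- build_flows(m)
  tc <- throughput_components(net)
  info <- information_indices(net)
  fci <- finn_cycling(net)
  tl <- solve_trophic_levels(m)
  omn <- omnivory(m, tl)
  spine <- suppressWarnings(lindeman_spine(m, net, tl))
  pz <- suppressWarnings(predation_mortality_stats(m))
  mtlco <- suppressWarnings(community_tl(m, tl))
  fish <- suppressWarnings(
    fishing_indicators(m, net, tl, tem = spine$TEm, calibration = calibration))
  data.frame(
    model = m$meta$name,
    TST = tc$TST, PP_TST = tc$PP_TST, FD_TST = tc$FD_TST, Q_TST = tc$Q_TST,
    R_TST = tc$R_TST, Ex_TST = tc$Ex_TST, PP_P = tc$PP_P,
    meanPz = pz[["meanPz"]], maxPz = pz[["maxPz"]], meanEE = mean_ee(m),
    TBco = tc$TBco, TB_TST = tc$TB_TST, mTLco = mtlco, TEm = spine$TEm,
    A_C = info$A_C, O_C = info$O_C, IFO = info$IFO_C, FCI = fci$FCI,
    SOI = omn$SOI, TC = fish$TC, TLc = fish$TLc, PPR_pct = fish$PPR_pct,
    L_index = fish$L_index, P_sust = fish$P_sust,
    stringsAsFactors = FALSE
  )
}

#' Key-role table of a model
#'
#' @param m A `food_web_model`.
#' @param ... Passed to [classify_roles()].
#' @return A classified `key_role_table` with a `model` column.
#' @export
key_role_table <- function(m, ...) {
  tbl <- classify_roles(key_indices(balance(m, warn = FALSE)), ...)
  cbind(model = m$meta$name, tbl)
}

#' Batch-compute indicators for a collection of models
#'
#' Computes the indicator row and key-role table of every model in a
#' directory of bundles or a list of models. Failures are isolated: a
#' malformed model yields a diagnostic row and the batch continues.
#'
#' @param models Either a directory containing model bundles
#'   (subdirectories or `.json` files readable by [load_model()]) or a
#'   (named) list of `food_web_model` objects.
#' @param traits Optional data frame of model traits (rows matched to
#'   models by name); vocabulary violations raise an error.
#' @param out_dir Optional output directory: writes `indicators.csv`,
#'   `keyroles.csv` and, on failures, `failures.csv`.
#' @param calibration P_sust calibration.
#' @return List with `indicators` (data frame), `keyroles` (data frame)
#'   and `failures` (data frame of model/error pairs).
#' @export
run_batch <- function(models, traits = NULL, out_dir = NULL,
                      calibration = psust_calibration()) {
  if (is.character(models)) {
    paths <- c(list.dirs(models, recursive = FALSE),
               list.files(models, pattern = "\\.json$", full.names = TRUE))
    loader <- function(p) load_model(p)
    items <- stats::setNames(paths, basename(paths))
  } else {
    loader <- identity
    items <- models
    if (is.null(names(items))) {
      names(items) <- vapply(items, function(m) m$meta$name, "")
    }
  }
  if (!is.null(traits)) check_trait_vocab(traits)
  ind <- list(); kr <- list(); failures <- list()
  for (nm in names(items)) {
    res <- tryCatch({
      m <- loader(items[[nm]])
      validate_model(m)
      m$meta$name <- nm
      list(ind = compute_indicators(m, calibration), kr = key_role_table(m))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[nm]] <- data.frame(model = nm, error = conditionMessage(res))
    } else {
      ind[[nm]] <- res$ind
      kr[[nm]] <- res$kr
    }
  }
  out <- list(indicators = do.call(rbind, c(ind, list(make.row.names = FALSE))),
              keyroles = do.call(rbind, c(kr, list(make.row.names = FALSE))),
              failures = if (length(failures))
                do.call(rbind, failures) else
                  data.frame(model = character(), error = character()))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$indicators, file.path(out_dir, "indicators.csv"),
                     row.names = FALSE)
    utils::write.csv(out$keyroles, file.path(out_dir, "keyroles.csv"),
                     row.names = FALSE)
    if (nrow(out$failures))
      utils::write.csv(out$failures, file.path(out_dir, "failures.csv"),
                       row.names = FALSE)
  }
  out
}

check_trait_vocab <- function(traits) {
  vocab <- trait_vocabularies()
  for (nm in intersect(names(traits), names(vocab))) {
    bad <- !is.na(traits[[nm]]) & !traits[[nm]] %in% vocab[[nm]]
    if (any(bad)) {
      stop("trait vocabulary violation in '", nm, "': ",
           paste(unique(traits[[nm]][bad]), collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Collection-level trait statistics
#'
#' Runs the PERMANOVA of the indicator table against one trait with the
#' structural covariates, and the chi-square decomposition of the
#' key-role by trait contingency table.
#'
#' @param indicators Indicator table from [run_batch()] (`model` column
#'   plus numeric indicators; columns with any `NA`, e.g. fishing
#'   indicators of unfished webs, are dropped with a message).
#' @param traits Trait data frame (rows matched to `indicators$model` by
#'   row name or a `model` column).
#' @param trait Name of the trait column to test.
#' @param covariates Covariate column names (default `n_groups`,
#'   `n_living`, `n_links`).
#' @param keyroles Optional key-role table from [run_batch()]; when given,
#'   the key-role x trait chi-square decomposition is also returned.
#' @param n_perm,seed Permutation control for [permanova()].
#' @return List with `permanova` and (optionally) `chisq`.
#' @export
run_stats <- function(indicators, traits, trait,
                      covariates = c("n_groups", "n_living", "n_links"),
                      keyroles = NULL, n_perm = 9999, seed = NULL) {
  stopifnot(trait %in% names(traits))
  if (!is.null(traits$model)) rownames(traits) <- traits$model
  tr <- traits[match(indicators$model, rownames(traits)), , drop = FALSE]
  x <- indicators[, setdiff(names(indicators), "model"), drop = FALSE]
  has_na <- vapply(x, anyNA, TRUE)
  if (any(has_na)) {
    message("dropping indicator column(s) with missing values: ",
            paste(names(x)[has_na], collapse = ", "))
    x <- x[, !has_na, drop = FALSE]
  }
  pm <- permanova(x, tr[[trait]],
                  covariates = tr[, intersect(covariates, names(tr)), drop = FALSE],
                  n_perm = n_perm, seed = seed)
  out <- list(permanova = pm)
  if (!is.null(keyroles)) {
    kr <- keyroles[!is.na(keyroles$role), ]
    lev <- tr[match(kr$model, indicators$model), trait]
    tab <- as.matrix(table(lev, kr$role))
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    out$chisq <- chisq_decomposition(tab)
  }
  out
}
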