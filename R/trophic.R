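#' Solve fractional trophic levels
#'
#' Trophic level is 1 for producers and detritus and
#' TL_j = 1 + (1 - pf_j) (sum_i DC\[i,j\] TL_i + import_j * TL_import)
#' for consumers (pf = producer fraction; imported diet is assigned
#' `import_tl`, default 1). The linear system has a unique solution for
#' any valid diet matrix whose cycles are not pure (all-cannibal) loops.
#'
#' @param m A `food_web_model`.
#' @param import_tl Trophic level assigned to imported diet (default 1).
#' @return Named numeric vector of trophic levels.
#' @export
#' @examples
#' solve_trophic_levels(fixture_chain3())
solve_trophic_levels <- function(m, import_tl = 1) {
  g <- m$groups
  n <- nrow(g)
  cons <- is_consumer(m)
  w <- ifelse(cons, 1 - g$producer_fraction, 0)
  # TL = 1 + w * (t(DC) %*% TL + import * import_tl)
  A <- diag(n) - (w * t(m$diet))
  b <- 1 + w * g$import_diet * import_tl
  tl <- tryCatch(solve(A, b),
                 error = function(e) stop("singular trophic-level system: ",
                                          conditionMessage(e)))
  stats::setNames(as.numeric(tl), g$name)
}

#' Mean trophic level of the community
#'
#' Biomass-weighted mean trophic level over groups with TL strictly
#' greater than 2 (the consumer community).
#'
#' @param m A `food_web_model`.
#' @param tl Trophic levels from [solve_trophic_levels()] (computed when
#'   missing).
#' @return Scalar; `NA` with a warning when no group has TL > 2.
#' @export
community_tl <- function(m, tl = solve_trophic_levels(m)) {
  keep <- tl > 2
  if (!any(keep)) {
    warning("no group with TL > 2; mTLco undefined")
    return(NA_real_)
  }
  sum(m$groups$B[keep] * tl[keep]) / sum(m$groups$B[keep])
}

#' Mean trophic level of the catch
#'
#' Catch-weighted mean trophic level of exploited groups; undefined (with
#' a warning) in unfished models.
#'
#' @inheritParams community_tl
#' @return Scalar `TLc`, or `NA` when total catch is zero.
#' @export
catch_tl <- function(m, tl = solve_trophic_levels(m)) {
  y <- m$groups$Y
  if (sum(y) <= 0) {
    warning("no catch; TLc undefined")
    return(NA_real_)
  }
  sum(y * tl) / sum(y)
}

#' Omnivory indices
#'
#' The omnivory index of a consumer is the diet-weighted variance of its
#' prey trophic levels around the mean prey level,
#' OI_j = sum_i DC\[i,j\] (TL_i - mean_prey_TL_j)^2 (imported diet enters
#' at the import trophic level). The system omnivory index aggregates OI
#' over consumers weighted by the logarithm of food intake; consumers with
#' intake at or below 1 t km-2 y-1 receive zero weight so the logarithm
#' stays nonnegative.
#'
#' @inheritParams community_tl
#' @param import_tl Trophic level of imported diet (default 1).
#' @return List with vector `OI` (per group; 0 for non-consumers) and
#'   scalar `SOI`.
#' @export
omnivory <- function(m, tl = solve_trophic_levels(m), import_tl = 1) {
  g <- m$groups
  n <- nrow(g)
  cons <- is_consumer(m)
  oi <- numeric(n)
  for (j in which(cons)) {
    wts <- c(m$diet[, j], g$import_diet[j])
    tls <- c(tl, import_tl)
    keep <- wts > 0
    if (!any(keep)) next
    mu <- sum(wts[keep] * tls[keep]) / sum(wts[keep])
    oi[j] <- sum(wts[keep] * (tls[keep] - mu)^2) / sum(wts[keep])
  }
  q <- consumption(m)
  w <- ifelse(cons & q > 1, log(pmax(q, 1)), 0)
  soi <- if (sum(w) > 0) sum(oi * w) / sum(w) else 0
  list(OI = stats::setNames(oi, g$name), SOI = soi)
}

#' Lindeman spine and transfer efficiencies
#'
#' Apportions every group's trophic activity to integer trophic levels:
#' producers and detritus sit entirely at level I; a consumer's
#' distribution is the diet-weighted average of its prey distributions
#' shifted up one level (imported diet enters at level I + 1). Throughput
#' of level k (k >= 2) is consumer intake apportioned by the spine; the
#' transfer efficiency of level k is the predation flow passed on to level
#' k+1 plus exports (catches and other export) leaving level k, relative
#' to the level's throughput. `TEm` is the geometric mean of TE for levels
#' II-IV, in percent; levels without throughput are dropped with a
#' warning.
#'
#' @param m A `food_web_model`.
#' @param net A `flow_network` from [build_flows()] (built when missing).
#' @param tl Trophic levels (solved when missing; used to size the spine).
#' @param max_level Hard cap on the number of integer levels (default 50).
#' @return List with matrix `spine` (levels x groups, rows of each group
#'   summing to 1 over levels), vector `TE` (per integer level, from level
#'   II), and scalar `TEm` (percent).
#' @export
lindeman_spine <- function(m, net = build_flows(m),
                           tl = solve_trophic_levels(m), max_level = 50) {
  g <- m$groups
  n <- nrow(g)
  cons <- is_consumer(m)
  K <- min(max_level, max(8L, ceiling(max(tl)) + 4L))
  # a[k, j]: fraction of group j's activity at integer level k
  a <- matrix(0, K, n, dimnames = list(NULL, g$name))
  a[1, ] <- ifelse(cons, g$producer_fraction, 1)
  for (k in 2:K) {
    prev <- a[k - 1, ]
    imp <- if (k == 2) g$import_diet else 0
    a[k, ] <- ifelse(cons, (1 - g$producer_fraction) *
                       (as.numeric(prev %*% m$diet) + imp), 0)
  }
  resid <- 1 - colSums(a)
  if (any(resid > 1e-6)) {
    warning("spine truncated at level ", K, "; max residual ",
            format(max(resid), digits = 3))
  }
  a <- sweep(a, 2, colSums(a), `/`)

  q <- consumption(m)
  # conditional distribution of consumption over levels >= 2
  acons <- a
  acons[1, ] <- 0
  cs <- colSums(acons)
  acons <- sweep(acons, 2, ifelse(cs > 0, cs, 1), `/`)
  thr <- as.numeric(acons %*% q)                       # level throughput, k>=2 rows meaningful
  pred_on <- rowSums(predation_flows(m))               # predation flow leaving each prey
  transfer <- as.numeric(a %*% pred_on)                # leaves level k for k+1
  exported <- as.numeric(a %*% (g$Y + g$E))
  te <- rep(NA_real_, K)
  for (k in 2:K) {
    if (thr[k] > 0) te[k] <- (transfer[k] + exported[k]) / thr[k]
  }
  lv <- 2:min(4, K)
  ok <- lv[!is.na(te[lv]) & te[lv] > 0]
  if (!length(ok)) {
    warning("no flow above trophic level I; TEm undefined")
    tem <- NA_real_
  } else {
    if (length(ok) < length(lv)) {
      warning("levels ", paste(setdiff(lv, ok), collapse = ", "),
              " carry no flow; dropped from TEm")
    }
    tem <- 100 * exp(mean(log(te[ok])))
  }
  list(spine = a, TE = stats::setNames(te[-1], paste0("TL", 2:K)), TEm = tem)
}
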