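#' Estimate ecotrophic efficiencies from the master balance equation
#'
#' For every living group i the production balance
#' B_i PB_i EE_i = sum_j Q_j DC\[i,j\] + Y_i + E_i + BA_i
#' is solved for EE_i: the fraction of production consumed by predators,
#' caught, exported or accumulated (the remainder flows to detritus).
#' For detritus pools EE is the fraction of detritus inflow that is
#' consumed by detritivores.
#'
#' @param m A validated `food_web_model`.
#' @return Named numeric vector of EE per group, in model order, with the
#'   balance report of [balance_report()] attached as attribute `"report"`.
#' @seealso [balance()] to write the estimates back onto the model.
#' @export
#' @examples
#' estimate_ee(fixture_chain3())
estimate_ee <- function(m) {
  g <- m$groups
  flows <- predation_flows(m)
  demand <- rowSums(flows) + g$Y + g$E + g$BA
  prod <- production(m)
  living <- is_living(m)
  ee <- rep(NA_real_, nrow(g))
  zero_prod <- living & prod <= 0 & demand > 0
  if (any(zero_prod)) {
    stop("unbalanced model: zero production with nonzero demand for ",
         paste(g$name[zero_prod], collapse = ", "))
  }
  ee[living] <- ifelse(prod[living] > 0, demand[living] / prod[living], 0)
  if (any(!living)) {
    inflow <- detritus_inflow(m, ee)
    det <- which(!living)
    ee[det] <- ifelse(inflow[det] > 0, demand[det] / inflow[det], 0)
  }
  names(ee) <- g$name
  attr(ee, "report") <- balance_report(m, ee)
  ee
}

# inflow to each detritus pool: egestion + non-utilized production of the
# living groups, split equally across detritus pools, plus detritus imports
detritus_inflow <- function(m, ee) {
  g <- m$groups
  living <- is_living(m)
  fd <- flow_to_detritus_vector(m, ee)
  ndet <- sum(!living)
  inflow <- numeric(nrow(g))
  if (ndet > 0) inflow[!living] <- sum(fd[living]) / ndet
  inflow
}

# per-group flow to detritus: unassimilated consumption + unutilized production
flow_to_detritus_vector <- function(m, ee) {
  g <- m$groups
  q <- consumption(m)
  prod <- production(m)
  fd <- g$GS * q + pmax(1 - pmin(ee, 1), 0) * prod
  fd[is_detritus(m)] <- 0
  fd[is.na(fd)] <- 0
  stats::setNames(fd, g$name)
}

#' Balance report for a food web model
#'
#' Summarizes the mass-balance diagnostics: per-group EE, the balance
#' residual of the master equation, and flags for EE exceeding 1 (the
#' model is then thermodynamically inconsistent; the condition is flagged,
#' never silently accepted).
#'
#' @param m A `food_web_model`.
#' @param ee EE vector; estimated with [estimate_ee()] when missing.
#' @return A data frame with columns `name`, `EE`, `residual`, `balanced`.
#' @export
balance_report <- function(m, ee = NULL) {
  if (is.null(ee)) ee <- c(estimate_ee(m))
  g <- m$groups
  prod <- production(m)
  flows <- predation_flows(m)
  demand <- rowSums(flows) + g$Y + g$E + g$BA
  residual <- ifelse(is_living(m), prod * ee - demand, 0)
  rel <- abs(residual) / pmax(abs(prod * ee), 1)
  data.frame(name = g$name, EE = as.numeric(ee), residual = rel,
             balanced = ee <= 1 + 1e-9, row.names = NULL)
}

#' @rdname estimate_ee
#' @param warn Warn when any estimated EE exceeds 1 (default `TRUE`).
#' @return [balance()] returns the model with `groups$EE` replaced by the
#'   estimates.
#' @export
balance <- function(m, warn = TRUE) {
  ee <- estimate_ee(m)
  if (warn && any(ee > 1 + 1e-9, na.rm = TRUE)) {
    warning("model is unbalanced: EE > 1 for ",
            paste(m$groups$name[which(ee > 1 + 1e-9)], collapse = ", "))
  }
  m$groups$EE <- as.numeric(ee)
  m
}

#' Mean ecotrophic efficiency
#'
#' Arithmetic mean of EE over living groups. Detritus EE has different
#' semantics (fraction of detritus inflow consumed) and is excluded; it is
#' available from [estimate_ee()] directly.
#'
#' @param m A `food_web_model`.
#' @return Scalar mean EE.
#' @export
mean_ee <- function(m) {
  ee <- m$groups$EE
  if (anyNA(ee[is_living(m)])) ee <- c(estimate_ee(m))
  mean(ee[is_living(m)])
}

#' Predation mortality statistics
#'
#' For every predator-prey pair with positive flow, the proportion of the
#' prey's total mortality attributable to that predator is
#' z_ij = (Q_j DC\[i,j\] / B_i) / PB_i. Returns the mean and maximum over
#' pairs.
#'
#' @param m A `food_web_model`.
#' @return Named vector `c(meanPz, maxPz)`; both `NA` (with a warning)
#'   when the web has no predation flows.
#' @export
predation_mortality_stats <- function(m) {
  g <- m$groups
  flows <- predation_flows(m)
  flows[is_detritus(m), ] <- 0   # detritivory is not predation mortality
  pairs <- which(flows > 0, arr.ind = TRUE)
  if (nrow(pairs) == 0) {
    warning("no predation flows; Pz undefined")
    return(c(meanPz = NA_real_, maxPz = NA_real_))
  }
  z <- flows[pairs] / (g$B[pairs[, 1]] * g$PB[pairs[, 1]])
  c(meanPz = mean(z), maxPz = max(z))
}
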