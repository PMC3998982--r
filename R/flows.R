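#' Build the flow network of a balanced model
#'
#' Converts a balanced model into the set of flows used by all network
#' indicators: the inter-compartment flow matrix `T` (predation flows
#' T\[i,j\] = Q_j DC\[i,j\], including detritivory), per-group imports
#' (primary production entering producers plus imported diet), exports
#' (catches, other export, biomass accumulation, detritus surplus),
#' respiration and flows to detritus.
#'
#' Respiration of a consumer is assimilation minus heterotrophic
#' production, (1 - GS) Q - (1 - producer_fraction) B PB; a negative value
#' indicates inconsistent rate inputs and is floored at zero with a
#' warning. Unconsumed detritus inflow leaves the system as export.
#'
#' @param m A `food_web_model`; EE is estimated if not already present.
#' @param tol Relative steady-state tolerance per compartment (default 1e-6).
#' @return A `flow_network` object: list with matrix `T`, vectors
#'   `imports`, `exports`, `respiration`, `flow_to_detritus`, component
#'   totals `Q_tot`, `R_tot`, `Ex_tot`, `FD_tot`, `PP_tot`, the four
#'   component `TST`, and bookkeeping fields (`living`, `names`).
#' @export
#' @examples
#' net <- build_flows(fixture_chain3())
#' net$TST
build_flows <- function(m, tol = 1e-6) {
  if (anyNA(m$groups$EE)) m <- balance(m, warn = TRUE)
  g <- m$groups
  n <- nrow(g)
  living <- is_living(m)
  ee <- g$EE
  q <- consumption(m)
  prod <- production(m)
  pp <- primary_production(m)

  Tm <- predation_flows(m)
  resp <- (1 - g$GS) * q - (1 - g$producer_fraction) * prod
  resp[q == 0] <- 0  # producers and detritus do not respire in this currency
  if (any(resp < -1e-12)) {
    warning("negative computed respiration floored at 0 for ",
            paste(g$name[resp < -1e-12], collapse = ", "),
            " (production exceeds assimilation)")
  }
  floored <- resp < -1e-12
  resp <- pmax(resp, 0)
  fd <- flow_to_detritus_vector(m, ee)

  imports <- pp + q * g$import_diet
  exports <- g$Y + g$E + g$BA
  # detritus surplus: inflow not consumed leaves the system
  det <- which(!living)
  if (length(det)) {
    inflow_det <- sum(fd[living]) / length(det)
    for (d in det) {
      surplus <- inflow_det - sum(Tm[d, ])
      if (surplus < -tol * max(inflow_det, 1)) {
        warning("detritus pool ", g$name[d], " is overconsumed (EE > 1)")
        surplus <- 0
      }
      exports[d] <- exports[d] + max(surplus, 0)
      imports[d] <- 0
    }
  }

  net <- structure(list(
    T = Tm, imports = stats::setNames(imports, g$name),
    exports = stats::setNames(exports, g$name),
    respiration = stats::setNames(resp, g$name),
    flow_to_detritus = fd,
    Q_tot = sum(q), R_tot = sum(resp), Ex_tot = sum(exports),
    FD_tot = sum(fd), PP_tot = sum(pp),
    TST = sum(q) + sum(exports) + sum(resp) + sum(fd),
    names = g$name, living = living, floored = floored, model = m
  ), class = "flow_network")

  check_steady_state(net, tol)
  net
}

# per-compartment input = output at steady state
check_steady_state <- function(net, tol = 1e-6) {
  n <- length(net$names)
  living <- net$living
  det_in <- numeric(n)
  if (any(!living)) det_in[!living] <- sum(net$flow_to_detritus) / sum(!living)
  input <- net$imports + colSums(net$T) + det_in
  output <- rowSums(net$T) + net$exports + net$respiration + net$flow_to_detritus
  rel <- abs(input - output) / pmax(input, output, 1e-12)
  bad <- rel > tol & (input + output) > 0 & !net$floored
  if (any(bad)) {
    stop("steady-state violation for compartment(s): ",
         paste(sprintf("%s (%.3g)", net$names[bad], rel[bad]), collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.flow_network <- function(x, ...) {
  cat("Flow network with", length(x$names), "compartments\n")
  cat(sprintf("  TST %.4g = Q %.4g + Ex %.4g + R %.4g + FD %.4g (t km-2 y-1)\n",
              x$TST, x$Q_tot, x$Ex_tot, x$R_tot, x$FD_tot))
  invisible(x)
}

#' Throughput components and biomass aggregates
#'
#' Total system throughput follows the Ecopath four-component convention,
#' TST = total consumption + total exports + total respiration + total
#' flows to detritus, so that the four component ratios sum to one.
#'
#' @param net A `flow_network`.
#' @return Named list: `TST`, `PP_TST`, `FD_TST`, `Q_TST`, `R_TST`,
#'   `Ex_TST`, `PP_P` (primary over total production), `TBco` (biomass of
#'   consumers, i.e. excluding detritus and pure primary producers),
#'   `TB_TST`, `TC` (total catch).
#' @export
throughput_components <- function(net) {
  if (net$TST <= 0) stop("TST is zero; empty network")
  m <- net$model
  g <- m$groups
  het_prod <- sum((1 - g$producer_fraction[is_living(m)]) *
                    production(m)[is_living(m)])
  tbco <- sum(g$B[is_consumer(m)])
  list(
    TST = net$TST,
    PP_TST = net$PP_tot / net$TST,
    FD_TST = net$FD_tot / net$TST,
    Q_TST = net$Q_tot / net$TST,
    R_TST = net$R_tot / net$TST,
    Ex_TST = net$Ex_tot / net$TST,
    PP_P = if (net$PP_tot + het_prod > 0) net$PP_tot / (net$PP_tot + het_prod) else NA_real_,
    TBco = tbco,
    TB_TST = tbco / net$TST,
    TC = sum(g$Y)
  )
}

#' Extended flow matrix
#'
#' Assembles the Ulanowicz-style extended matrix used by the information
#' and cycling indices: a virtual import row, the inter-compartment flows
#' (predation plus flows into detritus pools), and virtual export and
#' respiration sink columns.
#'
#' @param net A `flow_network`.
#' @return `(n+1) x (n+2)` matrix with dimnames
#'   `c("<import>", groups)` by `c(groups, "<export>", "<respiration>")`.
#' @export
extended_matrix <- function(net) {
  n <- length(net$names)
  Tm <- net$T
  det <- which(!net$living)
  if (length(det)) {
    per_det <- net$flow_to_detritus / length(det)
    for (d in det) Tm[, d] <- Tm[, d] + per_det
  }
  ext <- matrix(0, n + 1, n + 2,
                dimnames = list(c("<import>", net$names),
                                c(net$names, "<export>", "<respiration>")))
  ext[1, seq_len(n)] <- net$imports
  ext[2:(n + 1), seq_len(n)] <- Tm
  ext[2:(n + 1), n + 1] <- net$exports
  ext[2:(n + 1), n + 2] <- net$respiration
  ext
}

#' Write the extended flow matrix to CSV
#'
#' @param net A `flow_network`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_flow_matrix <- function(net, path) {
  utils::write.csv(as.data.frame(extended_matrix(net)), path)
  invisible(path)
}
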