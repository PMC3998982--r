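#' Flow information indices: capacity, ascendency, overhead, redundancy
#'
#' Computed on the extended flow matrix (virtual import row, export and
#' respiration sink columns; detritus internal). With T.. the total flow,
#' T_i. and T_.j the marginal row and column sums:
#' development capacity C = -sum T_ij log2(T_ij / T..),
#' ascendency A = sum T_ij log2(T_ij T.. / (T_i. T_.j)),
#' overhead O = C - A, and the internal-flow overhead (redundancy)
#' IFO = -sum over compartment-to-compartment pairs of
#' T_ij log2(T_ij^2 / (T_i. T_.j)). Flows are measured in bits (log base
#' 2); the relative indices A/C, O/C and IFO/C are base-invariant and are
#' reported in percent. A and O are additionally partitioned into import,
#' internal, export and dissipation components by flow class.
#'
#' @param net A `flow_network` from [build_flows()].
#' @return An `info_indices` list: `C`, `A`, `O`, `IFO` (flowbits),
#'   `A_C`, `O_C`, `IFO_C` (percent of C), and matrices `A_parts`,
#'   `O_parts` with the four-component partitions.
#' @export
#' @examples
#' information_indices(build_flows(fixture_chain3()))
information_indices <- function(net) {
  ext <- extended_matrix(net)
  tot <- sum(ext)
  if (tot <= 0) stop("all-zero network")
  rs <- rowSums(ext)
  cs <- colSums(ext)
  n <- length(net$names)

  idx <- which(ext > 0, arr.ind = TRUE)
  tij <- ext[idx]
  ri <- rs[idx[, 1]]
  cj <- cs[idx[, 2]]
  cap_terms <- -tij * log2(tij / tot)
  asc_terms <- tij * log2(tij * tot / (ri * cj))
  ovh_terms <- cap_terms - asc_terms        # = -T log2(T^2/(Ti. T.j))

  class_of <- function(i, j) {
    ifelse(i == 1, "import",
           ifelse(j == n + 1, "export",
                  ifelse(j == n + 2, "dissipation", "internal")))
  }
  cls <- factor(class_of(idx[, 1], idx[, 2]),
                levels = c("import", "internal", "export", "dissipation"))
  A_parts <- tapply(asc_terms, cls, sum, default = 0)
  O_parts <- tapply(ovh_terms, cls, sum, default = 0)

  C <- sum(cap_terms)
  A <- sum(asc_terms)
  O <- C - A
  IFO <- O_parts[["internal"]]
  structure(list(
    C = C, A = A, O = O, IFO = IFO,
    A_C = 100 * A / C, O_C = 100 * O / C, IFO_C = 100 * IFO / C,
    A_parts = A_parts, O_parts = O_parts
  ), class = "info_indices")
}

#' @export
print.info_indices <- function(x, ...) {
  cat(sprintf("C = %.4g, A = %.4g (%.1f%%), O = %.4g (%.1f%%), IFO = %.4g (%.1f%%) flowbits\n",
              x$C, x$A, x$A_C, x$O, x$O_C, x$IFO, x$IFO_C))
  invisible(x)
}

#' Finn cycling index
#'
#' Fraction of total system throughput that is recycled, from the
#' Leontief structure matrix of the input-fraction matrix G (G_ij =
#' T_ij / total input of j). With L = (I - G)^-1, the recycled flow of
#' compartment i is (L_ii - 1)/L_ii times its throughput (total inflow),
#' and TSTc is their sum.
#'
#' @param net A `flow_network`.
#' @param denominator `"ewe"` (default) divides TSTc by the four-component
#'   TST of [throughput_components()]; `"extended"` divides by the total
#'   of the extended flow matrix (the Finn convention).
#' @return List with `TSTc` (t km-2 y-1) and `FCI` (percent).
#' @export
#' @examples
#' finn_cycling(build_flows(fixture_chain3()))  # acyclic: FCI = 0
finn_cycling <- function(net, denominator = c("ewe", "extended")) {
  denominator <- match.arg(denominator)
  ext <- extended_matrix(net)
  n <- length(net$names)
  internal <- ext[-1, seq_len(n), drop = FALSE]     # compartment -> compartment
  inflow <- colSums(ext)[seq_len(n)]                # includes imports
  G <- sweep(internal, 2, ifelse(inflow > 0, inflow, 1), `/`)
  L <- tryCatch(solve(diag(n) - G),
                error = function(e) stop("singular (I - G); lossless cycle: ",
                                         conditionMessage(e)))
  dii <- diag(L)
  cycled <- ifelse(dii > 0, (dii - 1) / dii, 0) * inflow
  tstc <- sum(cycled)
  denom <- if (denominator == "ewe") net$TST else sum(ext)
  list(TSTc = tstc, FCI = 100 * tstc / denom)
}
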