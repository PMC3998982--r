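#' Mixed trophic impact matrix
#'
#' Quantifies the total (direct plus indirect) impact of every group on
#' every other. The direct impact of i on j combines the benefit of i as
#' food, DC\[i,j\], and the harm of i as predator, the share of total
#' predation on j that i exerts: q_ij = DC\[i,j\] - F_ji. Detritus pools
#' enter with a pseudo-diet given by the share of detritus inflow
#' contributed by each group, so that groups fuelling the detritus pool
#' impact it positively. Fishing fleets are not compartments. Total
#' impacts follow from the power-series closure
#' m = (I - q)^-1 - I.
#'
#' @param m A balanced `food_web_model`.
#' @return Square matrix `mti[i, j]` = impact of group i on group j
#'   (living groups and detritus, in model order).
#' @export
mti <- function(m) {
  if (anyNA(m$groups$EE)) m <- balance(m, warn = TRUE)
  g <- m$groups
  n <- nrow(g)
  dc <- m$diet
  det <- which(is_detritus(m))
  if (length(det)) {
    fd <- flow_to_detritus_vector(m, g$EE)
    tot_fd <- sum(fd)
    for (d in det) dc[, d] <- if (tot_fd > 0) fd / tot_fd else 0
  }
  flows <- predation_flows(m)           # prey x predator
  pred_tot <- rowSums(flows)
  Fshare <- sweep(flows, 1, ifelse(pred_tot > 0, pred_tot, 1), `/`)
  q <- dc - t(Fshare)                   # q[i, j]: impact of i on j
  out <- tryCatch(solve(diag(n) - q) - diag(n),
                  error = function(e) stop("singular MTI system: ",
                                           conditionMessage(e)))
  dimnames(out) <- list(g$name, g$name)
  out
}

#' Key-role indices from the mixed trophic impact matrix
#'
#' For each group i the overall effect is the Euclidean norm of its
#' impacts on the other compartments, eps_i = sqrt(sum_{j != i} m_ij^2)
#' (the self-impact m_ii is excluded); p_i is the group's share of living
#' biomass; keystoneness KS_i = log10(eps_i (1 - p_i)) is high for
#' low-biomass/high-impact groups and dominance KD_i = log10(eps_i p_i)
#' for high-biomass/high-impact groups; td_i is the percentage of the
#' squared overall effect exerted top-down (negative impacts).
#'
#' @param m A balanced `food_web_model`.
#' @param impact MTI matrix from [mti()] (computed when missing).
#' @param td_weighting `"squared"` (default, consistent with the
#'   Euclidean overall effect) or `"absolute"` for td.
#' @return A `key_role_table` data frame with columns `name`, `living`,
#'   `TL`, `eps`, `p`, `KS`, `KD`, `td`. KS and KD are `NA` for detritus
#'   (excluded from ranking) and for groups with zero overall effect.
#' @export
key_indices <- function(m, impact = mti(m),
                        td_weighting = c("squared", "absolute")) {
  td_weighting <- match.arg(td_weighting)
  g <- m$groups
  n <- nrow(g)
  living <- is_living(m)
  tl <- solve_trophic_levels(m)
  off <- impact
  diag(off) <- 0
  eps <- sqrt(rowSums(off^2))
  p <- rep(NA_real_, n)
  p[living] <- g$B[living] / sum(g$B[living])
  wfun <- if (td_weighting == "squared") function(x) x^2 else abs
  wneg <- rowSums(wfun(off) * (off < 0))
  wall <- rowSums(wfun(off))
  td <- ifelse(wall > 0, 100 * wneg / wall, NA_real_)
  ks <- kd <- rep(NA_real_, n)
  pos <- living & eps > 0
  ks[pos] <- log10(eps[pos] * (1 - p[pos]))
  kd[pos] <- log10(eps[pos] * p[pos])
  structure(
    data.frame(name = g$name, living = living, TL = as.numeric(tl),
               eps = eps, p = p, KS = ks, KD = kd, td = td,
               row.names = NULL),
    class = c("key_role_table", "data.frame")
  )
}

#' Classify key ecological roles
#'
#' Applies the key-role thresholds to a table of KS/KD indices: groups
#' with KS at or above `ks_threshold` are keystone, remaining groups with
#' KD at or above `kd_threshold` are structuring, the rest are other.
#' Detritus and groups without indices stay unclassified (`NA`).
#'
#' @param tbl A `key_role_table` (possibly row-bound over a collection).
#' @param ks_threshold Keystoneness threshold (default 0).
#' @param kd_threshold Dominance threshold (default -0.7; a published
#'   figure caption shows +0.7, treated as a typo but configurable here).
#' @return The table with a `role` factor column added, plus a `summary`
#'   attribute: counts and percentages per role over classified groups.
#' @export
classify_roles <- function(tbl, ks_threshold = 0, kd_threshold = -0.7) {
  role <- rep(NA_character_, nrow(tbl))
  scored <- !is.na(tbl$KS)
  role[scored] <- "other"
  role[scored & tbl$KD >= kd_threshold] <- "structuring"
  role[scored & tbl$KS >= ks_threshold] <- "keystone"
  tbl$role <- factor(role, levels = c("keystone", "structuring", "other"))
  counts <- table(tbl$role)
  attr(tbl, "summary") <- data.frame(
    role = names(counts),
    n = as.integer(counts),
    pct = round(100 * as.integer(counts) / sum(counts), 1)
  )
  tbl
}

#' Percentile cutoffs of key-role indices over a collection
#'
#' Recovers the KS and KD values marking the top fraction of ranked
#' groups across a model collection (e.g. the top 5%).
#'
#' @param tbl A `key_role_table` over a collection.
#' @param top Fraction treated as top-ranking (default 0.05).
#' @return Named vector `c(KS = , KD = )` of cutoff values.
#' @export
key_role_cutoffs <- function(tbl, top = 0.05) {
  c(KS = stats::quantile(tbl$KS, 1 - top, na.rm = TRUE, names = FALSE),
    KD = stats::quantile(tbl$KD, 1 - top, na.rm = TRUE, names = FALSE))
}
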