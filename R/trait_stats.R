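#' Distance-based permutational multivariate ANOVA with covariates
#'
#' One-way PERMANOVA of an indicator table against a categorical trait,
#' optionally preceded by numeric covariates, on Euclidean distances of
#' (by default) z-scored indicator columns. The pseudo-F statistic is
#' obtained by partitioning the Gower-centred inner-product matrix with
#' hat matrices of the sequentially nested designs (Type I sums of
#' squares). P-values come from permutations: raw-row permutation when
#' there are no covariates, and permutation of reduced-model residuals
#' (Freedman-Lane) for terms fitted after covariates.
#'
#' @param x Numeric matrix or data frame, rows = models, columns =
#'   indicators. Constant columns are dropped with a warning.
#' @param group Factor (or coercible) with at least two levels.
#' @param covariates Optional data frame / matrix of numeric covariates
#'   fitted before the factor.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed making the permutation p-values
#'   reproducible.
#' @param standardize Z-score columns before computing distances
#'   (default `TRUE`).
#' @return A `permanova` object: data frame `aov_table` with sequential
#'   `SS`, `df`, `pseudo_F` and permutation `p` per term, plus fields
#'   `SS_total`, `n_perm`.
#' @export
permanova <- function(x, group, covariates = NULL, n_perm = 999,
                      seed = NULL, standardize = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  group <- droplevels(as.factor(group))
  n <- nrow(x)
  if (nlevels(group) < 2) stop("group needs at least two levels")
  if (any(table(group) < 2)) stop("each group level needs at least two models")
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0 | is.na(sds))) {
      warning("dropping constant indicator column(s): ",
              paste(colnames(x)[sds == 0 | is.na(sds)], collapse = ", "))
      x <- x[, !(sds == 0 | is.na(sds)), drop = FALSE]
    }
    x <- scale(x)
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
  }

  d <- stats::dist(x)
  G <- gower_center(d)

  # sequential designs: intercept, + each covariate, + factor
  terms <- list()
  Z <- matrix(1, n, 1)
  designs <- list(Z)
  if (!is.null(covariates)) {
    for (nm in names(covariates)) {
      Z <- cbind(Z, as.numeric(covariates[[nm]]))
      designs[[length(designs) + 1]] <- Z
      terms[[length(terms) + 1]] <- nm
    }
  }
  Zf <- cbind(Z, stats::model.matrix(~group)[, -1, drop = FALSE])
  designs[[length(designs) + 1]] <- Zf
  terms[[length(terms) + 1]] <- "group"
  if (ncol(Zf) >= n) stop("fewer rows than model terms")

  hats <- lapply(designs, hat_matrix)
  ranks <- vapply(designs, function(z) qr(z)$rank, 0L)
  SS_total <- sum(diag(G))
  fits <- vapply(hats, function(h) sum(h * G), 0)  # tr(H G), H symmetric
  SS_terms <- diff(fits)
  df_terms <- diff(ranks)
  H_full <- hats[[length(hats)]]
  df_res <- n - ranks[length(ranks)]
  SS_res <- SS_total - fits[length(fits)]
  # terms aliased with earlier ones (rank unchanged) carry no df: F undefined
  Fs <- ifelse(df_terms > 0, (SS_terms / df_terms) / (SS_res / df_res),
               NA_real_)

  if (!is.null(seed)) set.seed(seed)
  R_full <- diag(n) - H_full
  pvals <- rep(NA_real_, length(terms))
  for (t in seq_along(terms)) {
    if (df_terms[t] == 0) next
    H_red <- hats[[t]]
    Hd <- hats[[t + 1]] - H_red
    R_red <- diag(n) - H_red
    G_res <- R_red %*% G %*% R_red
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      Gp <- G_res[p, p]
      f <- (sum(Hd * Gp) / df_terms[t]) / (sum(R_full * Gp) / df_res)
      if (f >= Fs[t] - 1e-12) exceed <- exceed + 1L
    }
    pvals[t] <- (exceed + 1) / (n_perm + 1)
  }

  structure(list(
    aov_table = data.frame(term = unlist(terms), df = df_terms,
                           SS = SS_terms, pseudo_F = Fs, p = pvals,
                           row.names = NULL),
    SS_total = SS_total, SS_residual = SS_res, df_residual = df_res,
    n_perm = n_perm
  ), class = "permanova")
}

gower_center <- function(d) {
  A <- -0.5 * as.matrix(d)^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

hat_matrix <- function(Z) {
  qz <- qr(Z)
  Q <- qr.Q(qz)[, seq_len(qz$rank), drop = FALSE]
  tcrossprod(Q)
}

#' @export
print.permanova <- function(x, ...) {
  cat("Distance-based PERMANOVA (sequential SS,", x$n_perm, "permutations)\n")
  tab <- x$aov_table
  tab$SS <- signif(tab$SS, 5)
  tab$pseudo_F <- signif(tab$pseudo_F, 5)
  print(tab, row.names = FALSE)
  cat(sprintf("Residual: df %d, SS %.5g; total SS %.5g\n",
              x$df_residual, x$SS_residual, x$SS_total))
  invisible(x)
}

#' Chi-square decomposition of a contingency table
#'
#' Decomposes the Pearson chi-square of an r x c table of counts into
#' per-cell contributions (O - E)^2 / E, with expected counts from the
#' product of margins. The per-cell contributions sum to the total
#' statistic; the p-value is the upper chi-square tail at
#' df = (r - 1)(c - 1).
#'
#' @param counts Matrix (or table) of nonnegative counts with positive
#'   margins.
#' @return A `chisq_decomp` list: `statistic`, `df`, `p_value`,
#'   `observed`, `expected`, `contributions`.
#' @export
#' @examples
#' chisq_decomposition(matrix(c(10, 0, 0, 10), 2))
chisq_decomposition <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(abs(counts - round(counts)) > 1e-8)) stop("counts must be integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero margin in contingency table")
  }
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  contrib <- (counts - E)^2 / E
  stat <- sum(contrib)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  structure(list(
    statistic = stat, df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE),
    observed = counts, expected = E, contributions = contrib
  ), class = "chisq_decomp")
}

#' @export
print.chisq_decomp <- function(x, ...) {
  cat(sprintf("Chi-square = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat("Per-cell contributions:\n")
  print(round(x$contributions, 3))
  invisible(x)
}

#' Correspondence analysis coordinates of a contingency table
#'
#' Singular value decomposition of the matrix of standardized residuals
#' (P_ij - r_i c_j) / sqrt(r_i c_j); principal row and column coordinates
#' reproduce chi-square / N as total inertia.
#'
#' @param counts Matrix of nonnegative counts.
#' @return List with `row`, `col` (principal coordinates), `sv`
#'   (singular values) and `inertia` (= sum of squared singular values).
#' @export
correspondence_coordinates <- function(counts) {
  counts <- as.matrix(counts)
  N <- sum(counts)
  if (N <= 0) stop("empty table")
  P <- counts / N
  r <- rowSums(P)
  c <- colSums(P)
  S <- (P - outer(r, c)) / sqrt(outer(r, c))
  dec <- svd(S)
  keep <- dec$d > 1e-12
  if (!any(keep)) {
    return(list(row = matrix(0, nrow(counts), 0),
                col = matrix(0, ncol(counts), 0),
                sv = numeric(0), inertia = 0))
  }
  d <- dec$d[keep]
  row <- sweep(dec$u[, keep, drop = FALSE], 1, sqrt(r), `/`) %*% diag(d, length(d))
  col <- sweep(dec$v[, keep, drop = FALSE], 1, sqrt(c), `/`) %*% diag(d, length(d))
  rownames(row) <- rownames(counts)
  rownames(col) <- colnames(counts)
  list(row = row, col = col, sv = d, inertia = sum(d^2))
}
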