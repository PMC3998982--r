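test_that("univariate pseudo-F equals the classical ANOVA F", {
  x <- c(0, 2, 4, 6, 1, 3)
  g <- factor(c("a", "a", "b", "b", "a", "b"))
  pm <- permanova(matrix(x), g, n_perm = 99, seed = 1, standardize = FALSE)
  f_aov <- summary(stats::aov(x ~ g))[[1]]$`F value`[1]
  expect_close(pm$aov_table$pseudo_F, f_aov, tol = 1e-10)
})

test_that("the 2-D toy partitions distances by hand", {
  x <- rbind(c(0, 0), c(0, 2), c(4, 0), c(4, 2))
  g <- factor(c("A", "A", "B", "B"))
  pm <- permanova(x, g, n_perm = 99, seed = 1, standardize = FALSE)
  expect_close(pm$SS_total, 20)
  expect_close(pm$SS_residual, 4)
  expect_close(pm$aov_table$SS, 16)
  expect_close(pm$aov_table$pseudo_F, 8)
})

test_that("permanova agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(21)
  x <- matrix(rnorm(60), 20, 3)
  g <- factor(rep(c("u", "v"), each = 10))
  pm <- permanova(x, g, n_perm = 199, seed = 3, standardize = FALSE)
  ref <- vegan::adonis2(dist(x) ~ g, permutations = 199)
  expect_close(pm$aov_table$pseudo_F, ref$F[1], tol = 1e-8)
  expect_close(pm$aov_table$SS, ref$SumOfSqs[1], tol = 1e-8)
})

test_that("sequential sums of squares add up with covariates", {
  set.seed(31)
  n <- 24
  cov <- data.frame(z1 = rnorm(n), z2 = runif(n))
  x <- matrix(rnorm(3 * n), n, 3) + cov$z1
  g <- factor(rep(letters[1:3], each = 8))
  pm <- permanova(x, g, covariates = cov, n_perm = 99, seed = 5)
  expect_close(sum(pm$aov_table$SS) + pm$SS_residual, pm$SS_total)
  expect_equal(pm$aov_table$term, c("z1", "z2", "group"))
  # p-values are reproducible under a fixed seed
  pm2 <- permanova(x, g, covariates = cov, n_perm = 99, seed = 5)
  expect_identical(pm$aov_table$p, pm2$aov_table$p)
})

test_that("constant indicator columns are dropped with a warning", {
  x <- cbind(rnorm(12), 1)
  g <- factor(rep(c("a", "b"), 6))
  expect_warning(pm <- permanova(x, g, n_perm = 49, seed = 1), "constant")
  expect_equal(ncol(pm$aov_table), 5)
})

test_that("chi-square decomposition matches hand arithmetic", {
  tab <- matrix(c(10, 0, 0, 10), 2, 2)
  cd <- chisq_decomposition(tab)
  expect_close(cd$statistic, 20)
  expect_equal(cd$df, 1)
  expect_close(sum(cd$contributions), cd$statistic)
  # a table equal to its expectation has statistic 0
  flat <- matrix(c(6, 6, 9, 9), 2, 2)
  expect_close(chisq_decomposition(flat)$statistic, 0)
  expect_error(chisq_decomposition(matrix(c(1, 0, 2, 0), 2, 2)), "margin")
  # agreement with the stock Pearson test
  set.seed(8)
  t2 <- matrix(rpois(12, 20), 3, 4)
  cd2 <- chisq_decomposition(t2)
  ref <- stats::chisq.test(t2, correct = FALSE)
  expect_close(cd2$statistic, unname(ref$statistic))
  expect_close(cd2$p_value, ref$p.value)
})

test_that("correspondence coordinates reproduce the chi-square inertia", {
  set.seed(9)
  tab <- matrix(rpois(9, 15) + 1, 3, 3)
  ca <- correspondence_coordinates(tab)
  cd <- chisq_decomposition(tab)
  expect_close(ca$inertia * sum(tab), cd$statistic)
  # independent eigen-decomposition oracle for the principal axis
  P <- tab / sum(tab); r <- rowSums(P); cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  ev <- eigen(t(S) %*% S)
  expect_close(ca$sv^2, ev$values[seq_along(ca$sv)], tol = 1e-8)
  # a 2x2 table has a single dimension
  expect_equal(length(correspondence_coordinates(matrix(c(8, 2, 3, 7), 2))$sv), 1)
})

test_that("type-I error of the permutation test is near nominal", {
  # both groups from the same spherical distribution: rejections ~ alpha
  set.seed(77)
  reps <- 200
  pvals <- numeric(reps)
  g <- factor(rep(c("a", "b"), each = 8))
  for (r in seq_len(reps)) {
    x <- matrix(rnorm(16 * 3), 16, 3)
    pvals[r] <- permanova(x, g, n_perm = 99)$aov_table$p
  }
  rate <- mean(pvals <= 0.05)
  ci <- stats::qbinom(c(0.005, 0.995), reps, 0.05) / reps
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})
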