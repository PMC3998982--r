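test_that("the 2-group MTI has the closed-form +-0.5 pattern", {
  m <- mti(two_group_model())
  expect_close(unname(m["P", "C"]), 0.5)   # prey feeds predator
  expect_close(unname(m["C", "P"]), -0.5)  # predator suppresses prey
  expect_close(unname(m["P", "P"]), -0.5)
  expect_close(unname(m["C", "C"]), -0.5)
})

test_that("a trophically isolated group has zero MTI row and column", {
  g <- data.frame(name = c("P", "H", "X"), role = c("producer", "consumer",
                                                    "producer"),
                  B = c(10, 1, 3), PB = c(10, 2, 5), QB = c(NA, 20, NA))
  d <- matrix(0, 3, 3); d[1, 2] <- 1
  m <- mti(food_web_model(g, d))
  expect_equal(unname(m["X", ]), rep(0, 3))
  expect_equal(unname(m[, "X"]), rep(0, 3))
})

test_that("the MTI closure equals the direct-impact path sum", {
  # the series representation only exists where it converges (dilute
  # interactions); strong-link webs are covered by the closed-form cases
  checked <- 0L
  for (s in 1:8) {
    w <- dilute_import_web(1100 + s)
    series <- mti_series_oracle(w)
    if (is.null(series)) next
    expect_equal(unname(mti(w)), unname(series), tolerance = 1e-6)
    checked <- checked + 1L
  }
  expect_gte(checked, 3L)
})

test_that("key indices follow their defining algebra on chain3", {
  m <- balance(fixture_chain3(), warn = FALSE)
  imp <- mti(m)
  tbl <- key_indices(m, imp)
  off <- imp; diag(off) <- 0
  eps <- sqrt(rowSums(off^2))
  b <- m$groups$B[1:3]
  p <- b / sum(b)
  expect_close(tbl$eps, unname(eps))
  expect_close(tbl$KS[1:3], unname(log10(eps[1:3] * (1 - p))))
  expect_close(tbl$KD[1:3], unname(log10(eps[1:3] * p)))
  # the scarce top carnivore is the most keystone living group
  expect_equal(which.max(tbl$KS), 3)
  # KS - KD = log10((1-p)/p) exactly
  expect_close(tbl$KS[1:3] - tbl$KD[1:3], log10((1 - p) / p))
  # detritus is excluded from ranking
  expect_true(is.na(tbl$KS[4]) && is.na(tbl$KD[4]))
})

test_that("top-down fractions follow the impact signs", {
  tbl <- key_indices(two_group_model())
  expect_equal(tbl$td[tbl$name == "C"], 100)  # predator acts top-down
  expect_equal(tbl$td[tbl$name == "P"], 0)    # prey acts bottom-up
})

test_that("KS - KD identity holds across generated webs", {
  for (s in 1:10) {
    w <- generate_web(web_config(n_groups = 9 + s, seed = 1200 + s))
    tbl <- key_indices(w)
    ok <- !is.na(tbl$KS)
    expect_close(tbl$KS[ok] - tbl$KD[ok],
                 log10((1 - tbl$p[ok]) / tbl$p[ok]))
  }
})

test_that("an engineered rare high-impact apex predator ranks first in KS", {
  tbl <- key_indices(keystone_web())
  expect_equal(tbl$name[which.max(tbl$KS)], "Apex")
})

test_that("role classification applies the thresholds", {
  tbl <- key_indices(keystone_web())
  cls <- classify_roles(tbl)
  expect_s3_class(cls$role, "factor")
  expect_true(all(cls$role[!is.na(cls$KS) & cls$KS >= 0] == "keystone"))
  # +Inf thresholds classify everything as other
  all_other <- classify_roles(tbl, ks_threshold = Inf, kd_threshold = Inf)
  expect_true(all(all_other$role[!is.na(all_other$role)] == "other"))
  smry <- attr(cls, "summary")
  expect_equal(sum(smry$n), sum(!is.na(cls$role)))
})

test_that("percentile cutoffs isolate the top-ranking fraction", {
  set.seed(11)
  webs <- lapply(1:6, function(s) generate_web(web_config(n_groups = 15,
                                                          seed = 1300 + s)))
  tbl <- do.call(rbind, lapply(webs, key_indices))
  cut <- key_role_cutoffs(tbl, top = 0.2)
  frac <- mean(tbl$KS >= cut["KS"], na.rm = TRUE)
  expect_equal(frac, 0.2, tolerance = 0.08)
})
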