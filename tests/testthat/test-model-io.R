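test_that("chain3 fixture round-trips through both bundle formats", {
  m <- fixture_chain3()
  dir <- file.path(tempdir(), "chain3_bundle")
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_equal(m2$groups$name, c("P", "H", "C", "D"))
  expect_equal(unname(m2$diet["H", "C"]), 1.0)
  expect_equal(m2$groups$B, m$groups$B)
  jf <- file.path(tempdir(), "chain3.json")
  save_model(m, jf)
  m3 <- load_model(jf)
  expect_equal(m3$diet, m$diet)
  expect_equal(m3$groups$QB, m$groups$QB)
})

test_that("save/load is lossless over seeded random webs", {
  for (s in c(1, 7, 23, 104)) {
    w <- generate_web(web_config(n_groups = 8 + (s %% 20), seed = s))
    dir <- file.path(tempdir(), paste0("web", s))
    save_model(w, dir)
    w2 <- load_model(dir)
    expect_equal(w2$groups$B, w$groups$B, tolerance = 1e-12)
    expect_equal(w2$diet, w$diet, tolerance = 1e-12)
    jf <- file.path(tempdir(), paste0("web", s, ".json"))
    save_model(w, jf)
    w3 <- load_model(jf)
    expect_equal(w3$groups$B, w$groups$B, tolerance = 1e-12)
    expect_equal(w3$diet, w$diet, tolerance = 1e-12)
  }
})

test_that("validation rejects malformed models with informative errors", {
  g <- data.frame(name = c("P", "H"), role = c("producer", "consumer"),
                  B = c(10, 1), PB = c(10, 2), QB = c(NA, 20))
  d <- matrix(c(0, 0, 0.8, 0), 2, 2)  # herbivore diet sums to 0.8
  expect_error(food_web_model(g, d), "diet column sum.*H")
  expect_error(food_web_model(g[, setdiff(names(g), "PB")],
                              matrix(0, 2, 2)), "PB")
  # missing file columns are named
  dir <- file.path(tempdir(), "broken_bundle")
  dir.create(dir, showWarnings = FALSE)
  utils::write.csv(g[, c("name", "role", "B")], file.path(dir, "groups.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(matrix(0, 2, 2)), file.path(dir, "diet.csv"))
  expect_error(load_model(dir), "PB")
  # opt-in renormalization is announced, never silent
  m <- food_web_model(g, d, validate = FALSE)
  expect_message(m2 <- validate_model(m, renormalize = TRUE), "renormalizing")
  expect_equal(sum(m2$diet[, 2]), 1)
})

test_that("EE estimation matches the hand energy balance on chain3", {
  m <- fixture_chain3()
  ee <- c(estimate_ee(m))
  expect_close(unname(ee[c("P", "H", "C")]), c(0.2, 0.25, 0.5))
  expect_close(mean_ee(m), (0.2 + 0.25 + 0.5) / 3)
  # doubling the catches doubles the carnivore EE to 1.0 (linearity)
  m2 <- m
  m2$groups$Y <- 2 * m2$groups$Y
  expect_close(unname(c(estimate_ee(m2))["C"]), 1.0)
  # a lone producer with no predators or catch has EE = 0
  solo <- food_web_model(
    data.frame(name = "P", role = "producer", B = 5, PB = 10),
    matrix(0, 1, 1))
  expect_equal(unname(c(estimate_ee(solo))), 0)
})

test_that("the balance identity holds and is order-invariant", {
  for (s in 1:20) {
    w <- generate_web(web_config(n_groups = 10 + s, seed = s))
    g <- w$groups
    rep <- balance_report(w)
    expect_true(all(rep$residual < 1e-9))
    expect_true(all(rep$balanced))
    # permuting group order leaves the EE estimates unchanged
    perm <- sample(nrow(g))
    wp <- food_web_model(g[perm, ], w$diet[perm, perm])
    expect_equal(c(estimate_ee(wp))[g$name], c(estimate_ee(w))[g$name],
                 tolerance = 1e-12)
    expect_equal(mean_ee(wp), mean_ee(w), tolerance = 1e-12)
  }
})

test_that("predation mortality stats match the chain3 hand oracle", {
  m <- fixture_chain3()
  pz <- predation_mortality_stats(m)
  expect_close(unname(pz["meanPz"]), mean(c(0.2, 0.25)))
  expect_close(unname(pz["maxPz"]), 0.25)
  # single predation pair: mean equals max
  pz2 <- predation_mortality_stats(two_group_model())
  expect_equal(unname(pz2["meanPz"]), unname(pz2["maxPz"]))
  # no predation at all: both missing, with a warning
  solo <- food_web_model(
    data.frame(name = "P", role = "producer", B = 5, PB = 10),
    matrix(0, 1, 1))
  expect_warning(pz3 <- predation_mortality_stats(solo), "no predation")
  expect_true(all(is.na(pz3)))
})

test_that("maxPz never exceeds the largest prey EE on balanced webs", {
  for (s in 1:25) {
    w <- generate_web(web_config(n_groups = 8 + (s %% 15), seed = 1000 + s))
    pz <- suppressWarnings(predation_mortality_stats(w))
    if (is.na(pz["maxPz"])) next
    expect_lte(pz[["maxPz"]], max(w$groups$EE[w$groups$role != "detritus"]) + 1e-9)
  }
})
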