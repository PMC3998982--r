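test_that("trophic levels solve the diet linear system", {
  expect_equal(unname(solve_trophic_levels(fixture_chain3())), c(1, 2, 3, 1))

  # mixed diet: 50% producer, 50% TL-2 herbivore -> TL 2.5
  g <- data.frame(name = c("P", "H", "O"), role = c("producer", "consumer",
                                                    "consumer"),
                  B = c(10, 1, 0.5), PB = c(10, 3, 1), QB = c(NA, 15, 6))
  d <- matrix(0, 3, 3); d[1, 2] <- 1; d[1:2, 3] <- 0.5
  expect_equal(unname(solve_trophic_levels(food_web_model(g, d))["O"]), 2.5)

  # mutual predation: A eats 50% producer + 50% B and vice versa -> TL 3
  g2 <- data.frame(name = c("P", "A", "B"), role = c("producer", "consumer",
                                                     "consumer"),
                   B = c(100, 1, 1), PB = c(10, 2, 2), QB = c(NA, 8, 8))
  d2 <- matrix(0, 3, 3)
  d2[c(1, 3), 2] <- 0.5
  d2[c(1, 2), 3] <- 0.5
  tl <- solve_trophic_levels(food_web_model(g2, d2))
  expect_close(unname(tl[c("A", "B")]), c(3, 3))

  # solution satisfies the defining linear system tightly
  for (s in 1:10) {
    w <- generate_web(web_config(n_groups = 9 + s, seed = 300 + s))
    tl <- solve_trophic_levels(w)
    cons <- w$groups$role == "consumer"
    rhs <- 1 + as.numeric(tl %*% w$diet) + w$groups$import_diet
    expect_equal(unname(tl[cons]), unname(rhs[cons]), tolerance = 1e-10)
  }
})

test_that("community and catch trophic levels weight correctly", {
  m <- fixture_chain3()
  tl <- solve_trophic_levels(m)
  expect_equal(community_tl(m, tl), 3)  # only C has TL > 2
  expect_equal(catch_tl(m, tl), 3)      # single caught group
  # equal biomasses at TL 3 and 4 average to 3.5; TL exactly 2 is excluded
  expect_equal(sum(c(1, 1) * c(3, 4)) / 2, 3.5)
  tl2 <- c(P = 1, H = 2, C = 3, D = 1)
  m2 <- m; m2$groups$B <- c(10, 5, 5, 1)
  expect_equal(community_tl(m2, tl2), 3)  # H at TL 2 never contributes
  # no catch: TLc undefined with a warning
  m3 <- m; m3$groups$Y <- 0
  expect_warning(v <- catch_tl(m3, tl), "no catch")
  expect_true(is.na(v))
})

test_that("omnivory is the variance of prey trophic levels", {
  m <- fixture_chain3()
  om <- omnivory(m)
  expect_equal(unname(om$OI), rep(0, 4))  # all monophagous
  expect_equal(om$SOI, 0)
  # 50/50 diet on TL 1 and TL 2 prey: variance 0.25
  g <- data.frame(name = c("P", "H", "O"), role = c("producer", "consumer",
                                                    "consumer"),
                  B = c(10, 1, 0.5), PB = c(10, 3, 1), QB = c(NA, 15, 6))
  d <- matrix(0, 3, 3); d[1, 2] <- 1; d[1:2, 3] <- 0.5
  m2 <- food_web_model(g, d)
  expect_close(unname(omnivory(m2)$OI["O"]), 0.25)
})

test_that("the Lindeman spine reproduces chain3 transfer efficiencies", {
  m <- fixture_chain3()
  sp <- suppressWarnings(lindeman_spine(m))
  expect_close(unname(sp$TE["TL2"]), 0.025)
  expect_close(unname(sp$TE["TL3"]), 0.1)
  expect_close(sp$TEm, 100 * sqrt(0.025 * 0.1))
  # a strict chain has a 0/1 spine
  expect_equal(unname(sp$spine[1:3, c("P", "H", "C")]), diag(3))
})

test_that("spine columns sum to one and TEm is scale-invariant", {
  for (s in 1:12) {
    w <- generate_web(web_config(n_groups = 8 + s, seed = 500 + s))
    net <- build_flows(w)
    sp <- suppressWarnings(lindeman_spine(w, net))
    expect_equal(unname(colSums(sp$spine)), rep(1, nrow(w$groups)),
                 tolerance = 1e-9)
    # uniform biomass rescaling leaves TEm unchanged
    ws <- w; ws$groups$B <- 2.5 * ws$groups$B; ws$groups$Y <- 2.5 * ws$groups$Y
    sps <- suppressWarnings(lindeman_spine(ws, build_flows(ws)))
    if (!is.na(sp$TEm)) expect_equal(sps$TEm, sp$TEm, tolerance = 1e-9)
  }
})
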