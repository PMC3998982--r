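# shared fixtures and independent oracles used across test files

# hand-built flow network (bypasses Ecopath bookkeeping) for toy topologies:
# flows[i, j] = flow from compartment i to compartment j
toy_network <- function(flows, imports, exports, respiration = 0 * imports,
                        tst = NULL) {
  n <- nrow(flows)
  nm <- rownames(flows)
  structure(list(
    T = flows,
    imports = stats::setNames(imports, nm),
    exports = stats::setNames(exports, nm),
    respiration = stats::setNames(respiration, nm),
    flow_to_detritus = stats::setNames(numeric(n), nm),
    Q_tot = sum(colSums(flows) + imports), R_tot = sum(respiration),
    Ex_tot = sum(exports), FD_tot = 0, PP_tot = 0,
    TST = if (is.null(tst)) sum(flows) + sum(imports) + sum(exports) +
      sum(respiration) else tst,
    names = nm, living = rep(TRUE, n), floored = rep(FALSE, n)
  ), class = "flow_network")
}

# two-group predator-prey model: consumer eats 100% of producer and is its
# only predator; the MTI closure has the closed-form +-0.5 pattern
two_group_model <- function() {
  g <- data.frame(name = c("P", "C"), role = c("producer", "consumer"),
                  B = c(10, 1), PB = c(5, 1), QB = c(NA, 5))
  d <- matrix(c(0, 0, 1, 0), 2, 2)
  food_web_model(g, d)
}

# engineered web with a rare apex predator that alone controls three
# abundant mid-level groups: the canonical keystone configuration
keystone_web <- function() {
  g <- data.frame(
    name = c("P", "H1", "H2", "C1", "Apex", "D"),
    role = c("producer", "consumer", "consumer", "consumer", "consumer",
             "detritus"),
    B = c(100, 20, 15, 5, 0.05, 50),
    PB = c(50, 5, 5, 2, 0.5, 0),
    QB = c(NA, 20, 20, 8, 3, NA)
  )
  d <- matrix(0, 6, 6, dimnames = list(g$name, g$name))
  d["P", "H1"] <- 1
  d[c("P", "D"), "H2"] <- c(0.7, 0.3)
  d[c("H1", "H2"), "C1"] <- c(0.5, 0.5)
  d[c("H1", "H2", "C1"), "Apex"] <- c(0.4, 0.3, 0.3)
  food_web_model(g, d)
}

# independent PPR oracle: enumerate all acyclic diet paths from each caught
# group down to producers/detritus, multiplying (Q/P) * DC at every step
ppr_path_oracle <- function(m) {
  g <- m$groups
  q <- enaweb::consumption(m)
  p <- enaweb::production(m)
  basal <- g$role != "consumer" | g$producer_fraction >= 1
  total <- 0
  walk <- function(j, demand, visited) {
    if (demand <= 0) return()
    if (basal[j]) { total <<- total + demand; return() }
    need <- demand * q[j] / p[j]
    for (i in which(m$diet[, j] > 0)) {
      if (i %in% visited) next
      walk(i, need * m$diet[i, j], c(visited, i))
    }
  }
  for (j in which(g$Y > 0)) walk(j, g$Y[j], j)
  unname(total)
}

# small web with import-dominated consumer diets: trophic interactions are
# dilute, so the mixed-trophic-impact path series converges and can serve
# as an independent oracle for the matrix-inverse closure
dilute_import_web <- function(seed, import = 0.7) {
  set.seed(seed)
  g <- data.frame(
    name = c("P1", "P2", "C1", "C2", "C3"),
    role = c("producer", "producer", "consumer", "consumer", "consumer"),
    B = c(50, 40, 5, 4, 2) * exp(stats::rnorm(5, 0, 0.2)),
    PB = c(30, 25, 6, 5, 3), QB = c(NA, NA, 25, 20, 12),
    import_diet = c(0, 0, import, import, import))
  d <- matrix(0, 5, 5, dimnames = list(g$name, g$name))
  for (j in 3:5) {
    prey <- seq_len(j - 1)
    w <- stats::rgamma(length(prey), 2)
    d[prey, j] <- (1 - import) * w / sum(w)
  }
  food_web_model(g, d)
}

# independent MTI oracle: rebuild the direct-impact matrix from first
# principles and sum the impact-path series, instead of inverting (I - q);
# returns NULL when the series does not converge (spectral radius >= 1)
mti_series_oracle <- function(m, tol = 1e-10, k_max = 5000) {
  m <- enaweb::balance(m, warn = FALSE)
  g <- m$groups
  n <- nrow(g)
  dc <- m$diet
  det <- which(g$role == "detritus")
  fd <- g$GS * enaweb::consumption(m) +
    (1 - pmin(g$EE, 1)) * enaweb::production(m)
  fd[det] <- 0
  for (dd in det) dc[, dd] <- fd / sum(fd)
  flows <- sweep(m$diet, 2, enaweb::consumption(m), `*`)
  ptot <- rowSums(flows)
  q <- dc - t(sweep(flows, 1, ifelse(ptot > 0, ptot, 1), `/`))
  if (max(Mod(eigen(q, only.values = TRUE)$values)) >= 0.999) return(NULL)
  series <- matrix(0, n, n)
  P <- diag(n)
  for (k in seq_len(k_max)) {
    P <- P %*% q
    series <- series + P
    if (max(abs(P)) < tol) break
  }
  series
}

# independent Finn oracle: Leontief series sum(G^k) instead of the inverse
finn_series_oracle <- function(net, k_max = 400) {
  ext <- enaweb::extended_matrix(net)
  n <- length(net$names)
  inflow <- colSums(ext)[seq_len(n)]
  G <- sweep(ext[-1, seq_len(n), drop = FALSE], 2,
             ifelse(inflow > 0, inflow, 1), `/`)
  L <- diag(n)
  P <- diag(n)
  for (k in seq_len(k_max)) {
    P <- P %*% G
    L <- L + P
  }
  dii <- diag(L)
  sum(ifelse(dii > 0, (dii - 1) / dii, 0) * inflow)
}

expect_close <- function(object, expected, tol = 1e-9) {
  expect_equal(object, expected, tolerance = tol)
}
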