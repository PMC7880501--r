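test_that("coalescence times reproduce the hand-solved small systems", {
  # two individuals coalesce in exactly one replacement event
  expect_equal(coalescence_times(complete_graph(2), "temperature")[1, 2], 1)
  # complete graph: tau = N - 1 by symmetry
  for (N in c(3, 5, 8)) {
    tau <- coalescence_times(complete_graph(N), "temperature")
    expect_equal(tau[upper.tri(tau)], rep(N - 1, N * (N - 1) / 2))
  }
  # star with two leaves, both schemes (2-unknown systems solved by hand)
  tauT <- coalescence_times(star_graph(2), "temperature")
  expect_equal(tauT[1, 2], 7 / 3)
  expect_equal(tauT[2, 3], 10 / 3)
  tauU <- coalescence_times(star_graph(2), "uniform")
  expect_equal(tauU[1, 2], 8 / 3)
  expect_equal(tauU[2, 3], 14 / 3)
})

test_that("tau is symmetric, positive off-diagonal, zero on the diagonal", {
  for (g in random_graph_pool(12)) {
    for (scheme in c("uniform", "temperature")) {
      tau <- coalescence_times(g, scheme)
      expect_equal(tau, t(tau))
      expect_equal(diag(tau), rep(0, g$N))
      expect_true(all(tau[upper.tri(tau)] > 0))
    }
  }
})

test_that("dense, sparse, and orbit-reduced solvers agree", {
  for (g in list(detour_graph(7, 3), cartwheel_graph(2, 3, 4, 0.5),
                 fan_graph(3, 2, 0.7), star_graph(5),
                 complete_bipartite_graph(2, 4))) {
    for (scheme in c("uniform", "temperature")) {
      td <- coalescence_times(g, scheme, method = "dense")
      ts <- coalescence_times(g, scheme, method = "sparse")
      to <- coalescence_times(g, scheme, method = "orbits")
      expect_lt(max(abs(td - ts)), 1e-9)
      expect_lt(max(abs(td - to)), 1e-9)
    }
  }
  gd <- random_connected_graph(7, directed = TRUE, weights = "uniform",
                               seed = 42)
  for (scheme in c("uniform", "temperature")) {
    expect_lt(max(abs(coalescence_times(gd, scheme, method = "dense") -
                      coalescence_times(gd, scheme, method = "sparse"))),
              1e-9)
  }
})

test_that("rho0 and rho' are affine in the initialization mixture", {
  g <- random_connected_graph(6, weights = "uniform", seed = 5)
  mu_u <- as.numeric(init_distribution(g, "uniform"))
  mu_t <- as.numeric(init_distribution(g, "temperature"))
  at <- function(lam) {
    ws <- weak_selection(g, lam * mu_u + (1 - lam) * mu_t)
    c(ws$rho0, ws$rho_prime)
  }
  ends <- cbind(at(0), at(1))
  for (lam in c(0.25, 0.5, 0.8)) {
    expect_equal(at(lam), as.numeric(ends %*% c(1 - lam, lam)),
                 tolerance = 1e-10)
  }
})

test_that("isothermal graphs give rho0 = 1/N and rho' = (N-1)/(2N)", {
  for (g in list(complete_graph(7), cycle_graph(8),
                 complete_bipartite_graph(3, 3),
                 fan_graph(3, 3, 1 / 4))) {
    for (scheme in c("uniform", "temperature")) {
      ws <- weak_selection(g, scheme)
      expect_equal(ws$rho0, 1 / g$N, tolerance = 1e-10)
      expect_equal(ws$rho_prime, (g$N - 1) / (2 * g$N), tolerance = 1e-10)
    }
  }
})

test_that("pipeline matches the exact Markov oracle on random graphs", {
  for (g in random_graph_pool(12, sizes = c(4, 5), seed0 = 600)) {
    for (scheme in c("uniform", "temperature")) {
      ws <- weak_selection(g, scheme)
      expect_equal(ws$rho0, exact_fixation(g, 1, scheme), tolerance = 1e-8)
      expect_equal(ws$rho_prime,
                   finite_difference_rho_prime(g, scheme, delta = 1e-3),
                   tolerance = 1e-4)
    }
  }
})

test_that("star summaries match the published closed forms over n", {
  for (n in c(2, 3, 5, 10, 25, 50)) {
    ws <- weak_selection(star_graph(n), "temperature")
    cf <- star_closed_form(n, "temperature")
    expect_equal(ws$rho0, cf$rho0, tolerance = 1e-10)
    expect_equal(ws$rho_prime, cf$rho_prime, tolerance = 1e-10)
    wsu <- weak_selection(star_graph(n), "uniform")
    cfu <- star_closed_form(n, "uniform")
    expect_equal(wsu$rho_prime, cfu$rho_prime, tolerance = 1e-10)
  }
})

test_that("temperature scheme couples relative and absolute effects", {
  # rho0 <= 1/N forces rho'/rho0 >= N rho'
  for (N in 4:6) {
    for (g in atlas_graphs(N)) {
      ws <- weak_selection(g, "temperature")
      if (ws$rho_prime > 0) {
        expect_gte(ws$ratio, ws$N * ws$rho_prime - 1e-10)
      }
    }
  }
})
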