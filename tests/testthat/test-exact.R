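test_that("exact solver matches the Moran formula on isothermal graphs", {
  expect_equal(exact_fixation(complete_graph(3), 2, "uniform"), 4 / 7,
               tolerance = 1e-12)
  for (g in list(complete_graph(5), cycle_graph(6),
                 complete_bipartite_graph(2, 2))) {
    for (r in c(0.6, 1, 1.7, 3)) {
      expect_equal(exact_fixation(g, r, "temperature"),
                   isothermal_fixation(g$N, r), tolerance = 1e-10)
      expect_equal(exact_fixation(g, r, "uniform"),
                   isothermal_fixation(g$N, r), tolerance = 1e-10)
    }
  }
  # neutral mutants under uniform initialization fix with probability 1/N
  for (g in random_graph_pool(6, sizes = c(4, 5), seed0 = 300)) {
    expect_equal(exact_fixation(g, 1, "uniform"), 1 / g$N, tolerance = 1e-10)
  }
})

test_that("automorphism lumping leaves exact probabilities unchanged", {
  for (g in list(star_graph(5), cartwheel_graph(2, 2, 3),
                 detour_graph(5, 3), fan_graph(2, 3, 0.4))) {
    g_plain <- g
    attr(g_plain, "aut_generators") <- NULL
    for (r in c(0.8, 1.3)) {
      expect_equal(exact_fixation(g, r, "temperature"),
                   exact_fixation(g_plain, r, "temperature"),
                   tolerance = 1e-12)
    }
  }
})

test_that("fixation probability increases with mutant fitness", {
  grid <- seq(0.5, 3, by = 0.25)
  for (g in list(star_graph(4), detour_graph(4, 2),
                 random_connected_graph(5, directed = TRUE, seed = 17))) {
    rho <- exact_fixation(g, grid, "temperature")
    expect_true(all(diff(rho) > 0))
  }
})

test_that("finite differences recover closed-form slopes", {
  expect_equal(finite_difference_rho_prime(complete_graph(4), "uniform",
                                           delta = 1e-3),
               3 / 8, tolerance = 1e-6)
  expect_equal(finite_difference_rho_prime(star_graph(2), "temperature",
                                           delta = 1e-3),
               14 / 45, tolerance = 1e-4)
  # Richardson extrapolation tightens the estimate
  plain <- finite_difference_rho_prime(star_graph(3), "uniform", delta = 5e-3)
  rich <- finite_difference_rho_prime(star_graph(3), "uniform", delta = 5e-3,
                                      richardson = TRUE)
  truth <- star_closed_form(3, "uniform")$rho_prime
  expect_lt(abs(rich - truth), abs(plain - truth))
})

test_that("the size limit of the exact solver is enforced", {
  expect_error(exact_fixation(complete_graph(15), 2), "N <= 14")
})

test_that("Monte Carlo simulation is reproducible and unbiased", {
  s1 <- simulate_fixation(complete_graph(3), 2, "uniform",
                          replicates = 4000, seed = 9)
  s2 <- simulate_fixation(complete_graph(3), 2, "uniform",
                          replicates = 4000, seed = 9)
  expect_identical(s1$estimate, s2$estimate)
  expect_lt(abs(s1$estimate - 4 / 7), 3 * s1$se + 1e-9)
  s3 <- simulate_fixation(complete_graph(5), 1, "uniform",
                          replicates = 4000, seed = 10)
  expect_lt(abs(s3$estimate - 0.2), 3 * s3$se + 1e-9)
})

test_that("difference curves vanish between equal-fixation graphs", {
  grid <- c(0.8, 1, 1.5, 2.5)
  k6 <- complete_graph(6)
  d <- fixation_difference_curve(k6, k6, grid, "temperature")
  expect_equal(d$difference, rep(0, length(grid)))
  iso <- fixation_difference_curve(cycle_graph(6), k6, grid, "temperature")
  expect_lt(max(abs(iso$difference)), 1e-10)
  expect_error(fixation_difference_curve(complete_graph(5), k6, grid),
               "same number")
})

test_that("the minimal absolute amplifier still loses to the complete graph", {
  bow <- bowtie_graph()
  expect_gt(finite_difference_rho_prime(bow, "temperature", delta = 1e-3),
            5 / 12)
  d <- fixation_difference_curve(bow, complete_graph(6),
                                 c(0.5, 1.5, 2, 3, 4), "temperature")
  expect_true(all(d$difference < 0))
})

test_that("sampled fixation curves respect the self-loop-free upper bound", {
  grid <- c(1.2, 2, 3, 5)
  for (g in list(star_graph(4), detour_graph(4, 2), bowtie_graph())) {
    expect_true(all(exact_fixation(g, grid, "temperature") <=
                      pavlogiannis_bound(grid) + 1e-12))
  }
})
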