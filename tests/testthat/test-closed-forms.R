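test_that("isothermal fixation formula and its weak-selection expansion", {
  expect_equal(isothermal_fixation(3, 2), 4 / 7)
  expect_equal(isothermal_fixation(10, 1), 1 / 10)
  for (N in c(4, 9)) {
    d <- 1e-4
    slope <- (isothermal_fixation(N, 1 + d) - isothermal_fixation(N, 1 - d)) /
      (2 * d)
    expect_equal(slope, (N - 1) / (2 * N), tolerance = 1e-6)
  }
})

test_that("star closed forms evaluate as published and reduce from bipartite", {
  cf <- star_closed_form(2, "temperature")
  expect_equal(cf$rho0, 4 / 15)
  expect_equal(cf$rho_prime, 14 / 45)
  cfu <- star_closed_form(2, "uniform")
  expect_equal(cfu$rho0, 1 / 3)
  expect_equal(cfu$rho_prime, 16 / 45)
  for (n in c(2, 4, 9)) {
    for (scheme in c("temperature", "uniform")) {
      s <- star_closed_form(n, scheme)
      b <- bipartite_closed_form(1, n, scheme)
      expect_equal(s$rho0, b$rho0)
      expect_equal(s$rho_prime, b$rho_prime)
    }
  }
})

test_that("balanced bipartite graphs recover the isothermal values", {
  for (k in c(2, 5, 12)) {
    cf <- bipartite_closed_form(k, k, "temperature")
    expect_equal(cf$rho0, 1 / (2 * k))
    expect_equal(cf$rho_prime, (2 * k - 1) / (4 * k))
  }
})

test_that("bipartite closed forms match the pipeline on a grid", {
  for (nA in 1:4) {
    for (nB in 2:5) {
      g <- complete_bipartite_graph(nA, nB)
      for (scheme in c("temperature", "uniform")) {
        ws <- weak_selection(g, scheme)
        cf <- bipartite_closed_form(nA, nB, scheme)
        expect_equal(ws$rho0, cf$rho0, tolerance = 1e-9)
        expect_equal(ws$rho_prime, cf$rho_prime, tolerance = 1e-9)
      }
    }
  }
})

test_that("unbalanced bipartite: absolute suppressor, relative amplifier", {
  for (nA in 1:5) {
    for (nB in (nA + 1):6) {
      cf <- bipartite_closed_form(nA, nB, "temperature")
      N <- nA + nB
      expect_lt(cf$rho_prime, (N - 1) / (2 * N))
      expect_gt(cf$ratio, (N - 1) / 2)
      expect_gt(bipartite_closed_form(nA, nB, "uniform")$rho_prime,
                (N - 1) / (2 * N))
    }
  }
})

test_that("cartwheel small-spoke slope: sign of h - m, well-mixed at h = m", {
  for (n in 2:3) for (m in 2:4) {
    cf <- cartwheel_limit_rho_prime(n, m, max(m, n))
    if (max(m, n) == m) {
      expect_equal(cf$rho_prime, (cf$N - 1) / (2 * cf$N))
    }
  }
  amp <- cartwheel_limit_rho_prime(4, 2, 4)   # h > m: amplifier at N = 12
  expect_gt(amp$rho_prime, 11 / 24)
  sup <- cartwheel_limit_rho_prime(2, 5, 2)   # h < m: suppressor at N = 12
  expect_lt(sup$rho_prime, 11 / 24)
})

test_that("cartwheel slope matches small-spoke numerics and the oracle slope", {
  for (par in list(c(2, 2, 3), c(3, 2, 3), c(2, 3, 2))) {
    n <- par[1]; m <- par[2]; h <- par[3]
    cf <- cartwheel_limit_rho_prime(n, m, h)
    ws <- weak_selection(cartwheel_graph(n, m, h, epsilon = 1e-6),
                         "temperature")
    expect_equal(ws$rho_prime, cf$rho_prime, tolerance = 1e-3)
    expect_equal(ws$rho0, 1 / cf$N, tolerance = 1e-3)
    # slope of the full fixation curve at r = 1 (numeric differentiation)
    d <- 1e-3
    slope <- (cartwheel_limit_fixation(n, m, h, 1 + d) -
                cartwheel_limit_fixation(n, m, h, 1 - d)) / (2 * d)
    expect_equal(slope, cf$rho_prime, tolerance = 1e-3)
  }
})

test_that("h = m cartwheel limit is exactly well-mixed for all fitness", {
  for (r in c(0.7, 1.3, 2.5)) {
    expect_equal(cartwheel_limit_fixation(2, 3, 3, r),
                 isothermal_fixation(9, r))
  }
  expect_error(cartwheel_limit_fixation(10, 3, 10, 2), "N <= 14")
})

test_that("narrow spider cartwheels out-amplify the same-size star (relative)", {
  for (n in 7:9) {
    g <- cartwheel_graph(n, 2, n, epsilon = 1e-4)
    ws <- weak_selection(g, "temperature")
    star <- star_closed_form(3 * n - 1, "temperature")
    expect_gt(ws$ratio, star$ratio)
  }
})

test_that("spider limit: one-third jump, monotone, below the upper bound", {
  eps <- 1e-9
  expect_equal(spider_limit_fixation(1 + eps), 1 / 3, tolerance = 1e-8)
  expect_equal(spider_limit_fixation(0.99), 0)
  expect_equal(spider_limit_fixation(2), 11 / 18)
  rs <- exp(seq(log(1 + 1e-6), log(100), length.out = 200))
  vals <- spider_limit_fixation(rs)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals <= pavlogiannis_bound(rs)))
  expect_equal(spider_limit_fixation(1e8), 1, tolerance = 1e-7)
})

test_that("self-loop-free bound evaluates as stated", {
  expect_equal(pavlogiannis_bound(1), 1 / 2)
  expect_equal(pavlogiannis_bound(2), 2 / 3)
})

test_that("fan closed forms match the pipeline across the release grid", {
  for (scheme in c("temperature", "uniform")) {
    for (n in 2:4) {
      for (m in 2:4) {
        for (eps in c(0.1, (m - 1) / (m * n - 1), 1, 10)) {
          g <- fan_graph(n, m, eps)
          ws <- weak_selection(g, scheme)
          cf <- fan_closed_form(n, m, eps, scheme)
          expect_equal(ws$rho0, cf$rho0, tolerance = 1e-9)
          expect_equal(ws$rho_prime, cf$rho_prime, tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("fan limits: isothermal point, star limit, large-n slope", {
  for (n in 2:3) for (m in 2:3) {
    eps <- (m - 1) / (m * n - 1)
    cf <- fan_closed_form(n, m, eps, "temperature")
    expect_equal(cf$rho_prime, (cf$N - 1) / (2 * cf$N), tolerance = 1e-12)
    expect_equal(cf$rho0, 1 / cf$N, tolerance = 1e-12)
    # eps -> infinity approaches the star S_{nm}
    big <- fan_closed_form(n, m, 1e8, "temperature")
    star <- star_closed_form(n * m, "temperature")
    expect_equal(big$rho0, star$rho0, tolerance = 1e-5)
    expect_equal(big$rho_prime, star$rho_prime, tolerance = 1e-5)
  }
  # rho' -> (m+1)/(2m) as n grows
  m <- 3
  n <- 1e6
  expect_equal(fan_closed_form(n, m, sqrt((m - 1) / (m * n)),
                               "temperature")$rho_prime,
               (m + 1) / (2 * m), tolerance = 1e-2)
  expect_equal(fan_closed_form(n, m, 0.5, "uniform")$rho_prime,
               (m + 1) / (2 * m), tolerance = 1e-2)
})

test_that("the fan walks through all three classifications as eps grows", {
  n <- 3; m <- 2
  N <- n * m + 1
  eps_iso <- (m - 1) / (m * n - 1)
  low <- fan_closed_form(n, m, eps_iso / 4, "temperature")
  expect_lt(low$rho_prime, (N - 1) / (2 * N))
  expect_lt(low$ratio, (N - 1) / 2)
  mid <- fan_closed_form(n, m, eps_iso * 1.5, "temperature")
  expect_gt(mid$rho_prime, (N - 1) / (2 * N))
  expect_gt(mid$ratio, (N - 1) / 2)
  high <- fan_closed_form(n, m, 50, "temperature")
  expect_lt(high$rho_prime, (N - 1) / (2 * N))
  expect_gt(high$ratio, (N - 1) / 2)
})
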