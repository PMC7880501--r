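## Closed-form weak-selection results for named families, each
## cross-validated against the numeric coalescence pipeline in the test
## suite.

#' Well-mixed / isothermal fixation probability
#'
#' `rho(r) = (1 - 1/r) / (1 - r^-N)`: the Moran fixation probability of a
#' fitness-`r` mutant in a well-mixed population, valid for every isothermal
#' graph of size `N` (Isothermal Theorem). Continuous at `r = 1` where the
#' value is `1/N`.
#'
#' @param N Population size (>= 2).
#' @param r Mutant fitness (> 0); vectorized.
#' @return Fixation probability.
#' @export
isothermal_fixation <- function(N, r) {
  if (any(r <= 0)) stop("mutant fitness must be positive")
  ifelse(abs(r - 1) < 1e-12,
         1 / N + (r - 1) * (N - 1) / (2 * N),  # Taylor at neutrality
         (1 - 1 / r) / (1 - r^(-N)))
}

#' Star closed forms
#'
#' Weak-selection coefficients for the Star with `n` leaves (`N = n + 1`).
#' Temperature: `rho0 = 2n / ((n+1)(n^2+1))`,
#' `rho' = n(2n^2 - n + 1) / ((n+1)^2 (n^2+1))` -- an absolute suppressor
#' but relative amplifier at every size. Uniform: `rho0 = 1/(n+1)`,
#' `rho' = n^2 (n^2 - n + 2) / ((n+1)^2 (n^2+1))` -- an amplifier, with
#' `rho' -> 1` as `n` grows.
#'
#' @param n Number of leaves (>= 2); vectorized.
#' @param scheme `"temperature"` or `"uniform"`.
#' @return List with vectors `rho0`, `rho_prime`, `ratio`.
#' @export
star_closed_form <- function(n, scheme = c("temperature", "uniform")) {
  scheme <- match.arg(scheme)
  if (any(n < 2)) stop("'n' must be >= 2")
  if (scheme == "temperature") {
    rho0 <- 2 * n / ((n + 1) * (n^2 + 1))
    rp <- n * (2 * n^2 - n + 1) / ((n + 1)^2 * (n^2 + 1))
  } else {
    rho0 <- 1 / (n + 1)
    rp <- n^2 * (n^2 - n + 2) / ((n + 1)^2 * (n^2 + 1))
  }
  list(rho0 = rho0, rho_prime = rp, ratio = rp / rho0)
}

#' Complete bipartite closed forms
#'
#' Temperature: `rho0 = 2 nA nB / ((nA+nB)(nA^2+nB^2))`,
#' `rho' = nA nB (2(nA^2+nB^2) - (nA+nB)) / ((nA+nB)^2 (nA^2+nB^2))`.
#' Uniform: `rho0 = 1/N`,
#' `rho' = ((nA^2+nB^2)^2 - (nA^3+nB^3)) / ((nA+nB)^2 (nA^2+nB^2))`.
#' Reduces to the Star forms at `nA = 1` and to the isothermal values at
#' `nA = nB`.
#'
#' @param nA,nB Part sizes (>= 1); vectorized.
#' @param scheme `"temperature"` or `"uniform"`.
#' @return List with vectors `rho0`, `rho_prime`, `ratio`.
#' @export
bipartite_closed_form <- function(nA, nB, scheme = c("temperature", "uniform")) {
  scheme <- match.arg(scheme)
  if (any(nA < 1) || any(nB < 1)) stop("part sizes must be >= 1")
  s2 <- nA^2 + nB^2
  if (scheme == "temperature") {
    rho0 <- 2 * nA * nB / ((nA + nB) * s2)
    rp <- nA * nB * (2 * s2 - (nA + nB)) / ((nA + nB)^2 * s2)
  } else {
    rho0 <- 1 / (nA + nB)
    rp <- (s2^2 - (nA^3 + nB^3)) / ((nA + nB)^2 * s2)
  }
  list(rho0 = rho0, rho_prime = rp, ratio = rp / rho0)
}

#' Cartwheel weak-selection slope in the small-spoke limit
#'
#' As the spoke weight vanishes, `rho0 -> 1/N` (both schemes coincide) and
#' the slope is
#' `rho' = (N-1)/(2N) + m n h (h - m) (m(n-2)(h-1) + h(m-1)) /
#'   (2 (h(m-1) + m(h-1)) (mn + h) (mn(h-1) + h(m-1)))`
#' with `N = n m + h`. The correction carries the sign of `h - m`: larger
#' hubs amplify, larger islands suppress, and `h = m` recovers the
#' well-mixed slope exactly.
#'
#' @param n Number of islands (>= 1).
#' @param m Island size (>= 1).
#' @param h Hub size (>= `n`).
#' @return List with `rho0`, `rho_prime`, `ratio`, `N`.
#' @export
cartwheel_limit_rho_prime <- function(n, m, h) {
  if (any(h < n) || any(n < 1) || any(m < 1)) {
    stop("need h >= n >= 1 and m >= 1")
  }
  N <- n * m + h
  rp <- (N - 1) / (2 * N) +
    m * n * h * (h - m) * (m * (n - 2) * (h - 1) + h * (m - 1)) /
    (2 * (h * (m - 1) + m * (h - 1)) * (m * n + h) *
       (m * n * (h - 1) + h * (m - 1)))
  list(rho0 = 1 / N, rho_prime = rp, ratio = N * rp, N = N)
}

#' Cartwheel fixation probability in the small-spoke limit
#'
#' For `h = m` the limit is exactly the well-mixed formula of size
#' `N = nm + m`, for any fitness. For `h != m` no reliably transcribable
#' closed form is available; instead, when `N <= 14`, the function evaluates
#' the exact `2^N`-state solver on the Cartwheel with a small spoke weight
#' `epsilon` (temperature initialization; the two schemes coincide in the
#' limit). Larger general cases are refused -- use
#' [cartwheel_limit_rho_prime()] for the weak-selection slope.
#'
#' @param n Number of islands (>= 1).
#' @param m Island size (>= 1).
#' @param h Hub size (>= `n`).
#' @param r Mutant fitness (> 0); vectorized.
#' @param epsilon Spoke weight used for the numeric route (default `1e-6`).
#' @return Fixation probability in the `epsilon -> 0` limit.
#' @export
cartwheel_limit_fixation <- function(n, m, h, r, epsilon = 1e-6) {
  if (h == m) return(isothermal_fixation(m * n + m, r))
  N <- n * m + h
  if (N > MAX_EXACT_N) {
    stop("general-case Cartwheel limit is only available numerically for ",
         "N <= ", MAX_EXACT_N, "; use cartwheel_limit_rho_prime() for the ",
         "weak-selection slope")
  }
  g <- cartwheel_graph(n, m, h, epsilon = epsilon)
  exact_fixation(g, r, "temperature")
}

#' Spider limit fixation probability
#'
#' The Cartwheel with `m = 2`, `h = n` and vanishing spoke weight, as the
#' number of legs grows without bound: `rho(r) = (1 - r^-2 / 3) / (1 + r^-1)`
#' for `r > 1`, and 0 for `r < 1`. Fixation probability jumps from 0 to 1/3
#' as the mutant turns beneficial, making this limit an especially strong
#' amplifier; the curve stays below the `1 - 1/(r+1)` self-loop-free bound.
#'
#' @param r Mutant fitness; vectorized.
#' @return Fixation probability in the double limit.
#' @export
spider_limit_fixation <- function(r) {
  ifelse(r > 1, (1 - r^(-2) / 3) / (1 + 1 / r), 0)
}

#' Upper bound on fixation probability without self-loops
#'
#' `1 - 1/(r + 1)`: no weighted graph without self-loops can exceed this
#' fixation probability under temperature initialization.
#'
#' @param r Mutant fitness (> 0); vectorized.
#' @return The bound.
#' @export
pavlogiannis_bound <- function(r) {
  if (any(r <= 0)) stop("mutant fitness must be positive")
  1 - 1 / (r + 1)
}

#' Fan closed forms
#'
#' Rational-function expressions for `rho0` and `rho'` of the Fan
#' `F_{n,m}` with hub-blade weight `epsilon`, derived symbolically from the
#' reproductive-value and pair-coalescence systems (the blade symmetry
#' reduces the pair system to three unknowns). They satisfy every limit the
#' family is known for: the isothermal point `epsilon = (m-1)/(mn-1)` gives
#' `(1/N, (N-1)/(2N))`; `epsilon -> Inf` approaches the Star `S_{nm}`; and
#' `rho' -> (m+1)/(2m)` as `n -> Inf` (with `epsilon ~ sqrt((m-1)/(mn))`
#' under temperature initialization, or fixed `epsilon` under uniform).
#'
#' @param n Number of blades (>= 2).
#' @param m Blade size (>= 2).
#' @param epsilon Hub-blade weight (> 0).
#' @param scheme `"temperature"` or `"uniform"`.
#' @return List with `rho0`, `rho_prime`, `ratio`, `N`.
#' @export
fan_closed_form <- function(n, m, epsilon,
                            scheme = c("temperature", "uniform")) {
  scheme <- match.arg(scheme)
  if (any(n < 2) || any(m < 2)) stop("need n >= 2 and m >= 2")
  if (any(epsilon <= 0)) stop("'epsilon' must be > 0")
  e <- epsilon
  N <- m * n + 1
  rho0 <- if (scheme == "temperature") {
    m * n * e * ((m - 1) * (m * n + 2) + 2 * e) /
      ((m * n + 1) * (m - 1 + e) * (m - 1 + e * (m^2 * n^2 + 1)))
  } else {
    1 / N
  }
  # shared denominator factor: (m-1+e)^2 + mn(1+e)(m-1+e) + m^3 n^2 e
  q <- (m - 1 + e)^2 + m * n * (1 + e) * (m - 1 + e) + m^3 * n^2 * e
  if (scheme == "temperature") {
    num <- m * n * e * (2 * (m - 1 + e)^3 +
      2 * m * n * (m - 1 + e)^2 * (2 * m - 1 - e) +
      2 * m^2 * n^2 * (m - 1 + e) * (2 * e^2 - e + m^2 - m) +
      m^4 * n^3 * e * (2 * (m + 2 * e - 1) + n * (m^2 - 1)))
    den <- 2 * (m - 1 + e) * (m * n + 1) * (m - 1 + e * (m^2 * n^2 + 1)) * q
  } else {
    num <- m^2 * n^2 * e * (m^3 * (m + 1) * n^3 * e +
      2 * m^2 * n^2 * (e - 1) * e +
      m * n * (3 * m - 2 * e + 1) * (m + e - 1) +
      4 * (m + e - 1)^2)
    den <- 2 * (m * n + 1) * (m^2 * n^2 * e + m + e - 1) * q
  }
  rp <- num / den
  list(rho0 = rho0, rho_prime = rp, ratio = rp / rho0, N = N)
}
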