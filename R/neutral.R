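## Neutral drift: reproductive values, initialization schemes, and the
## neutral fixation probability rho0.

#' Initial-mutant placement distribution
#'
#' Probability `mu_i` that the single initial mutant arises at vertex `i`.
#' `"uniform"` (`mu_i = 1/N`) models mutations striking all individuals
#' equally; `"temperature"` (`mu_i = T_i/N`) models mutations arising in new
#' offspring, so hot vertices -- those replaced often -- seed more mutants.
#'
#' @param g An [evograph()].
#' @param scheme `"uniform"`, `"temperature"`, or `"custom"`.
#' @param mu Probability vector over vertices, required when
#'   `scheme = "custom"`.
#' @return Numeric vector of length `N` with attribute `scheme`.
#' @export
init_distribution <- function(g, scheme = c("uniform", "temperature", "custom"),
                              mu = NULL) {
  scheme <- match.arg(scheme)
  out <- switch(scheme,
    uniform = rep(1 / g$N, g$N),
    temperature = temperatures(g) / g$N,
    custom = {
      if (is.null(mu)) stop("custom scheme requires 'mu'")
      if (length(mu) != g$N) stop("'mu' must have one entry per vertex")
      if (any(mu < 0) || abs(sum(mu) - 1) > 1e-12) {
        stop("'mu' must be a probability vector summing to 1")
      }
      as.numeric(mu)
    })
  structure(out, scheme = scheme)
}

# accept either a scheme name or a numeric mu vector
resolve_mu <- function(g, scheme) {
  if (is.numeric(scheme)) {
    init_distribution(g, "custom", mu = scheme)
  } else {
    init_distribution(g, scheme)
  }
}

#' Reproductive values
#'
#' `pi_i` is the fixation probability of a single neutral mutant placed at
#' vertex `i`. The vector solves the balance system
#' `T_i pi_i = sum_j p_ij pi_j` with `sum_i pi_i = 1`. For undirected graphs
#' the solution is in closed form: `pi_i` is inversely proportional to the
#' weighted degree `w_i`. For digraphs the (rank-deficient by one) balance
#' system is solved with the last balance equation replaced by the
#' normalization, which is well conditioned for strongly connected graphs.
#'
#' @param g A strongly connected [evograph()].
#' @return Numeric vector of length `N`, positive, summing to 1.
#' @export
reproductive_values <- function(g) {
  if (!is_strongly_connected(g)) stop("graph must be strongly connected")
  if (!g$directed) {
    inv <- 1 / weighted_degrees(g)
    return(inv / sum(inv))
  }
  p <- step_probabilities(g)
  A <- diag(temperatures(g)) - p
  A[g$N, ] <- 1
  b <- c(numeric(g$N - 1L), 1)
  pi_ <- tryCatch(solve(A, b), error = function(e) {
    stop("reproductive-value system is numerically singular: ",
         conditionMessage(e))
  })
  if (any(pi_ <= 0)) stop("non-positive reproductive value: system ill-posed")
  pi_
}

#' Neutral fixation probability
#'
#' `rho0 = sum_i mu_i pi_i`: the probability that a neutral mutant, placed
#' according to the initialization scheme, takes over the population. Under
#' uniform initialization `rho0 = 1/N` for every graph; under temperature
#' initialization `rho0 <= 1/N`, with equality exactly on isothermal graphs,
#' so structure can only slow the neutral molecular clock.
#'
#' @param g A strongly connected [evograph()].
#' @param scheme Initialization scheme name, or a custom probability vector.
#' @return A probability.
#' @export
neutral_fixation <- function(g, scheme = "temperature") {
  mu <- resolve_mu(g, scheme)
  sum(mu * reproductive_values(g))
}
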