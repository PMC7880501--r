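## Pair coalescence times and the weak-selection coefficient rho'.
##
## Under neutral drift the ancestral lineages of two vertices perform
## coalescing random walks; tau_ij is the expected (initialization-rescaled)
## time for the lineages of i and j to meet. The unordered-pair linear system
##
##   tau_ij = [ N (mu_i + mu_j) + sum_k (p_ki tau_kj + p_kj tau_ki) ] / (T_i + T_j)
##
## with tau_ii = 0 has N(N-1)/2 unknowns and a unique solution on strongly
## connected graphs. The whole numerator is divided by T_i + T_j: with
## mu = T/N this reduces to the "1 + ..." coalescence form, and on K_2 it
## gives tau = 1 (one replacement event coalesces the pair).

pair_index <- function(N) {
  idx <- matrix(0L, N, N)
  up <- which(upper.tri(idx))
  idx[up] <- seq_along(up)
  idx[lower.tri(idx)] <- t(idx)[lower.tri(idx)]
  idx
}

#' Pair coalescence times
#'
#' Solves the pair system for a strongly connected graph and placement
#' distribution. Three solvers share the same solution: a dense solver
#' (default for small graphs), a sparse solver (`Matrix`), and an
#' orbit-reduced solver that collapses vertex pairs into equivalence classes
#' under graph automorphisms, used automatically when the graph carries
#' automorphism generators (family constructors attach them) and the
#' placement distribution is symmetry-invariant.
#'
#' @param g A strongly connected [evograph()].
#' @param scheme Initialization scheme name (`"uniform"`, `"temperature"`)
#'   or a custom probability vector.
#' @param method `"auto"`, `"dense"`, `"sparse"`, or `"orbits"`.
#' @param check Verify the recurrence residual (default `TRUE`).
#' @return `N x N` symmetric matrix with zero diagonal.
#' @export
coalescence_times <- function(g, scheme = "temperature",
                              method = c("auto", "dense", "sparse", "orbits"),
                              check = TRUE) {
  method <- match.arg(method)
  if (!is_strongly_connected(g)) stop("graph must be strongly connected")
  mu <- resolve_mu(g, scheme)
  p <- step_probabilities(g)
  Tv <- colSums(p)
  if (method == "auto") {
    gens <- aut_generators(g)
    ok <- !is.null(gens) && length(gens) > 0 &&
      all(vapply(gens, function(s) max(abs(mu[s] - mu)), 0) < 1e-12)
    method <- if (ok) "orbits" else if (g$N <= 60) "dense" else "sparse"
  }
  tau <- switch(method,
    dense = coalescence_dense(g, p, Tv, mu),
    sparse = coalescence_sparse(g, p, Tv, mu),
    orbits = coalescence_orbits(g, p, Tv, mu))
  if (check) {
    S <- crossprod(p, tau)
    R <- outer(Tv, Tv, "+") * tau - g$N * outer(mu, mu, "+") - S - t(S)
    diag(R) <- 0
    if (max(abs(R)) > 1e-8 * max(1, max(tau))) {
      stop("coalescence system residual too large: numerical failure")
    }
  }
  tau
}

coalescence_dense <- function(g, p, Tv, mu) {
  N <- g$N
  idx <- pair_index(N)
  M <- N * (N - 1L) / 2L
  A <- matrix(0, M, M)
  rhs <- numeric(M)
  up <- which(upper.tri(idx), arr.ind = TRUE)
  for (r in seq_len(M)) {
    i <- up[r, 1]; j <- up[r, 2]
    ks <- which(p[, i] > 0)
    ks <- ks[ks != j]
    if (length(ks)) {
      cols <- idx[cbind(ks, rep(j, length(ks)))]
      A[r, cols] <- A[r, cols] - p[ks, i]
    }
    ks <- which(p[, j] > 0)
    ks <- ks[ks != i]
    if (length(ks)) {
      cols <- idx[cbind(ks, rep(i, length(ks)))]
      A[r, cols] <- A[r, cols] - p[ks, j]
    }
    A[r, r] <- A[r, r] + Tv[i] + Tv[j]
    rhs[r] <- N * (mu[i] + mu[j])
  }
  tvec <- solve(A, rhs)
  tau <- matrix(0, N, N)
  tau[upper.tri(tau)] <- tvec
  tau + t(tau)
}

coalescence_sparse <- function(g, p, Tv, mu) {
  N <- g$N
  idx <- pair_index(N)
  M <- N * (N - 1L) / 2L
  edges <- which(p > 0, arr.ind = TRUE)  # (k, i): offspring of k replaces i
  trip_i <- vector("list", nrow(edges) + 1L)
  trip_j <- vector("list", nrow(edges) + 1L)
  trip_x <- vector("list", nrow(edges) + 1L)
  for (e in seq_len(nrow(edges))) {
    k <- edges[e, 1]; i <- edges[e, 2]
    js <- seq_len(N)[-c(i, k)]
    trip_i[[e]] <- idx[cbind(rep(i, length(js)), js)]
    trip_j[[e]] <- idx[cbind(rep(k, length(js)), js)]
    trip_x[[e]] <- rep(-p[k, i], length(js))
  }
  up <- which(upper.tri(idx), arr.ind = TRUE)
  trip_i[[nrow(edges) + 1L]] <- seq_len(M)
  trip_j[[nrow(edges) + 1L]] <- seq_len(M)
  trip_x[[nrow(edges) + 1L]] <- Tv[up[, 1]] + Tv[up[, 2]]
  A <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x), dims = c(M, M))
  rhs <- N * (mu[up[, 1]] + mu[up[, 2]])
  tvec <- as.numeric(Matrix::solve(A, rhs))
  tau <- matrix(0, N, N)
  tau[upper.tri(tau)] <- tvec
  tau + t(tau)
}

# union-find orbit computation over pair indices
pair_orbits <- function(N, gens, w) {
  for (s in gens) {
    if (length(s) != N || !setequal(s, seq_len(N))) {
      stop("automorphism generator is not a permutation of the vertices")
    }
    if (max(abs(w[s, s] - w)) != 0) {
      stop("supplied permutation is not a graph automorphism")
    }
  }
  idx <- pair_index(N)
  up <- which(upper.tri(idx), arr.ind = TRUE)
  M <- nrow(up)
  parent <- seq_len(M)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (s in gens) {
    img <- idx[cbind(s[up[, 1]], s[up[, 2]])]
    for (r in seq_len(M)) {
      a <- find(r); b <- find(img[r])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(M), find, 0L)
  cls <- match(roots, unique(roots))
  list(idx = idx, up = up, cls = cls, K = max(cls))
}

coalescence_orbits <- function(g, p, Tv, mu) {
  N <- g$N
  orb <- pair_orbits(N, aut_generators(g), g$w)
  reps <- match(seq_len(orb$K), orb$cls)  # one representative pair per class
  A <- matrix(0, orb$K, orb$K)
  rhs <- numeric(orb$K)
  for (r in seq_len(orb$K)) {
    i <- orb$up[reps[r], 1]; j <- orb$up[reps[r], 2]
    for (pair in list(c(i, j), c(j, i))) {
      a <- pair[1]; b <- pair[2]
      ks <- which(p[, a] > 0)
      ks <- ks[ks != b]
      if (length(ks)) {
        cols <- orb$cls[orb$idx[cbind(ks, rep(b, length(ks)))]]
        for (t in seq_along(ks)) A[r, cols[t]] <- A[r, cols[t]] - p[ks[t], a]
      }
    }
    A[r, r] <- A[r, r] + Tv[i] + Tv[j]
    rhs[r] <- N * (mu[i] + mu[j])
  }
  tcls <- solve(A, rhs)
  tau <- matrix(0, N, N)
  tau[upper.tri(tau)] <- tcls[orb$cls]
  tau + t(tau)
}

#' Weak-selection coefficient
#'
#' `rho' = d rho(r) / dr` at `r = 1`: the slope of fixation probability in
#' mutant fitness at neutrality, computed from coalescence times as
#' `rho' = (1/2N) sum_ij p_ij pi_j tau_ij`. On undirected graphs this equals
#' the degree-weighted form `(1/(2 N Wtilde)) sum_ij w_ij tau_ij / (w_i w_j)`
#' with `Wtilde = sum_i 1/w_i`; the reproductive-value weighting extends it
#' to digraphs and is validated against a finite-difference oracle.
#'
#' @param g A strongly connected [evograph()].
#' @param scheme Initialization scheme name or custom probability vector.
#' @param tau Optional precomputed [coalescence_times()] matrix for the same
#'   scheme.
#' @param method Passed to [coalescence_times()].
#' @return The dimensionless slope `rho'`.
#' @export
weak_selection_coefficient <- function(g, scheme = "temperature", tau = NULL,
                                       method = "auto") {
  if (is.null(tau)) tau <- coalescence_times(g, scheme, method = method)
  p <- step_probabilities(g)
  pi_ <- reproductive_values(g)
  sum(p * tau * matrix(pi_, g$N, g$N, byrow = TRUE)) / (2 * g$N)
}

#' Weak-selection summary
#'
#' Computes the pair `(rho0, rho')` of the weak-selection expansion
#' `rho(1 + delta) = rho0 + delta rho' + O(delta^2)` for one graph and
#' initialization scheme, in polynomial time (the pair system has
#' `N(N-1)/2` unknowns). Isothermal graphs give exactly
#' `(1/N, (N-1)/(2N))`.
#'
#' @inheritParams weak_selection_coefficient
#' @return List with elements `N`, `scheme`, `rho0`, `rho_prime`, and
#'   `ratio` (`rho'/rho0`, the weak-selection analogue of a dN/dS-type
#'   substitution-rate ratio).
#' @export
weak_selection <- function(g, scheme = "temperature", method = "auto") {
  mu <- resolve_mu(g, scheme)
  pi_ <- reproductive_values(g)
  rho0 <- sum(mu * pi_)
  tau <- coalescence_times(g, scheme, method = method)
  p <- step_probabilities(g)
  rp <- sum(p * tau * matrix(pi_, g$N, g$N, byrow = TRUE)) / (2 * g$N)
  list(N = g$N,
       scheme = if (is.numeric(scheme)) "custom" else scheme,
       rho0 = rho0, rho_prime = rp, ratio = rp / rho0)
}
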