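## Exact ground truth for small graphs: the Birth-death process is an
## absorbing Markov chain on the 2^N mutant-occupancy states; absorption
## probabilities into the all-mutant state are solved directly. The state
## space is bitmask-ordered, absorbing states eliminated, and the system
## solved sparsely; mutant-birth coefficients enter linearly in r, so the
## assembled structure is reused across fitness values (for curves and
## root finding).

MAX_EXACT_N <- 14L

# occupancy-state orbits under graph automorphisms: states in one orbit have
# identical absorption probability, so the 2^N system can be solved on orbit
# representatives only (exact lumping, not an approximation)
state_classes <- function(N, gens, bits) {
  n_states <- 2^N
  pow <- 2^(seq_len(N) - 1)
  parent <- seq_len(n_states)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (s in gens) {
    inv <- order(s)
    img <- as.integer(bits[, inv, drop = FALSE] %*% pow) + 1L
    for (r in seq_len(n_states)) {
      a <- find(r); b <- find(img[r])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n_states), find, 0L)
  match(roots, unique(roots))
}

exact_structure <- function(g) {
  N <- g$N
  if (N > MAX_EXACT_N) {
    stop(sprintf("exact solver limited to N <= %d (state space 2^N); got %d",
                 MAX_EXACT_N, N))
  }
  p <- step_probabilities(g)
  Tv <- colSums(p)
  n_states <- 2^N
  bits <- matrix(FALSE, n_states, N)
  for (v in seq_len(N)) {
    bits[, v] <- bitwAnd(seq_len(n_states) - 1L, bitwShiftL(1L, v - 1L)) > 0
  }
  gens <- aut_generators(g)
  gens <- Filter(function(s) max(abs(g$w[s, s] - g$w)) == 0, as.list(gens))
  cls <- if (length(gens)) state_classes(N, gens, bits) else seq_len(n_states)
  reps <- match(seq_len(max(cls)), cls)          # representative state per class
  transient <- reps[reps != 1L & reps != n_states]
  row_of_class <- integer(max(cls))
  row_of_class[cls[transient]] <- seq_along(transient)
  row_of <- row_of_class[cls]                    # state id -> equation row
  ti <- tj <- vector("list", length(transient))
  tx <- vector("list", length(transient))
  mutant_flag <- vector("list", length(transient))
  kcount <- integer(length(transient))
  for (s in transient) {
    r <- row_of[s]
    inS <- bits[s, ]
    a <- colSums(p[inS, , drop = FALSE])  # sum_{i in S} p_ij
    k <- sum(inS)
    kcount[r] <- k
    up_j <- which(!inS & a > 0)           # mutant birth into j
    down_j <- which(inS & (Tv - a) > 0)   # resident birth into j
    s_up <- s + bitwShiftL(1L, up_j - 1L)
    s_down <- s - bitwShiftL(1L, down_j - 1L)
    ti[[r]] <- rep.int(r, length(up_j) + length(down_j))
    tj[[r]] <- c(s_up, s_down)            # state ids; mapped to rows later
    tx[[r]] <- c(a[up_j], (Tv - a)[down_j])
    mutant_flag[[r]] <- rep(c(TRUE, FALSE), c(length(up_j), length(down_j)))
  }
  ti <- unlist(ti); tj <- unlist(tj); tx <- unlist(tx)
  mf <- unlist(mutant_flag)
  n_trans <- length(transient)
  row_sum <- function(flag) {  # total outflow coefficient per row
    out <- numeric(n_trans)
    if (any(flag)) {
      rs <- rowsum(tx[flag], ti[flag])
      out[as.integer(rownames(rs))] <- rs[, 1]
    }
    out
  }
  to_full <- tj == n_states
  keep <- tj != 1L & !to_full
  list(N = N, n_trans = n_trans, row_of = row_of, kcount = kcount,
       bits = bits,
       ti_m = ti[keep & mf], tj_m = row_of[tj[keep & mf]], tx_m = tx[keep & mf],
       ti_r = ti[keep & !mf], tj_r = row_of[tj[keep & !mf]], tx_r = tx[keep & !mf],
       bfull_i = ti[to_full], bfull_x = tx[to_full], bfull_m = mf[to_full],
       row_m_sum = row_sum(mf), row_r_sum = row_sum(!mf))
}

# absorption probabilities (into all-mutant) from every transient state
exact_absorption <- function(st, r) {
  # equation per transient state s (multiplied through by total fitness):
  #   (r * sum_mutant_coeffs + sum_resident_coeffs) x_s =
  #     sum r a_j x_{s+j} + sum (T_j - a_j) x_{s-j} + [boundary to full]
  d <- r * st$row_m_sum + st$row_r_sum
  A <- Matrix::sparseMatrix(
    i = c(seq_len(st$n_trans), st$ti_m, st$ti_r),
    j = c(seq_len(st$n_trans), st$tj_m, st$tj_r),
    x = c(d, -r * st$tx_m, -st$tx_r),
    dims = c(st$n_trans, st$n_trans))
  b <- numeric(st$n_trans)
  bx <- ifelse(st$bfull_m, r * st$bfull_x, st$bfull_x)
  for (q in seq_along(st$bfull_i)) {
    b[st$bfull_i[q]] <- b[st$bfull_i[q]] + bx[q]
  }
  as.numeric(Matrix::solve(A, b))
}

#' Exact fixation probability
#'
#' Solves the full `2^N`-state absorbing Markov chain of the Birth-death
#' process for the probability that the mutant lineage fixes, averaged over
#' the initial placement distribution. Feasible for `N <= 14`.
#'
#' @param g A strongly connected [evograph()] with `N <= 14`.
#' @param r Mutant fitness (> 0). May be a vector.
#' @param scheme Initialization scheme name or custom probability vector.
#' @return Fixation probability (vectorized over `r`).
#' @export
exact_fixation <- function(g, r, scheme = "temperature") {
  if (any(r <= 0)) stop("mutant fitness must be positive")
  if (!is_strongly_connected(g)) stop("graph must be strongly connected")
  mu <- resolve_mu(g, scheme)
  st <- exact_structure(g)
  singles <- st$row_of[1L + bitwShiftL(1L, seq_len(g$N) - 1L)]
  vapply(r, function(rr) {
    x <- exact_absorption(st, rr)
    sum(mu * x[singles])
  }, 0)
}

#' Finite-difference weak-selection coefficient
#'
#' Central difference `[rho(1+delta) - rho(1-delta)] / (2 delta)` on the
#' exact solver: the independent oracle for the coalescence-pipeline
#' `rho'`, accurate to `O(delta^2)` (or `O(delta^4)` with Richardson
#' extrapolation over `delta` and `delta/2`).
#'
#' @param g A strongly connected [evograph()] with `N <= 14`.
#' @param scheme Initialization scheme name or custom probability vector.
#' @param delta Step size in fitness (0 < delta <= 0.01).
#' @param richardson Use Richardson extrapolation? Default `FALSE`.
#' @return Estimate of `rho'`.
#' @export
finite_difference_rho_prime <- function(g, scheme = "temperature",
                                        delta = 1e-3, richardson = FALSE) {
  if (delta <= 0 || delta > 0.01) stop("'delta' must be in (0, 0.01]")
  fd <- function(d) {
    v <- exact_fixation(g, c(1 + d, 1 - d), scheme)
    (v[1] - v[2]) / (2 * d)
  }
  if (!richardson) return(fd(delta))
  (4 * fd(delta / 2) - fd(delta)) / 3
}

#' Monte Carlo fixation estimate
#'
#' Simulates the Birth-death process to absorption and reports the fixation
#' frequency with its binomial standard error. Reproducible for a fixed
#' seed; no step cap is applied by default (absorption is certain on
#' strongly connected graphs).
#'
#' @param g A strongly connected [evograph()].
#' @param r Mutant fitness (> 0).
#' @param scheme Initialization scheme name or custom probability vector.
#' @param replicates Number of independent runs.
#' @param seed Integer seed (required).
#' @param max_steps Optional step cap; capped runs are censored (counted as
#'   non-fixation) and their number reported.
#' @return List with `estimate`, `se`, `replicates`, `censored`.
#' @export
simulate_fixation <- function(g, r, scheme = "temperature", replicates = 1000,
                              seed, max_steps = Inf) {
  if (r <= 0) stop("mutant fitness must be positive")
  if (missing(seed)) stop("'seed' is required")
  if (replicates < 1) stop("need at least one replicate")
  mu <- resolve_mu(g, scheme)
  p <- step_probabilities(g)
  N <- g$N
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fixed <- 0L
  censored <- 0L
  for (rep in seq_len(replicates)) {
    mut <- logical(N)
    mut[sample.int(N, 1, prob = mu)] <- TRUE
    steps <- 0
    while (TRUE) {
      k <- sum(mut)
      if (k == 0L || k == N) break
      if (steps >= max_steps) { censored <- censored + 1L; break }
      f <- ifelse(mut, r, 1)
      i <- sample.int(N, 1, prob = f)
      j <- sample.int(N, 1, prob = p[i, ])
      mut[j] <- mut[i]
      steps <- steps + 1
    }
    if (sum(mut) == N) fixed <- fixed + 1L
  }
  est <- fixed / replicates
  list(estimate = est, se = sqrt(est * (1 - est) / replicates),
       replicates = replicates, censored = censored)
}

#' Fixation-probability difference curve
#'
#' `rho_g(r) - rho_ref(r)` over a fitness grid, both sides computed with the
#' exact solver. Used to compare a structured population against the
#' same-size well-mixed baseline over the full fitness range.
#'
#' @param g,reference Strongly connected [evograph()] objects of equal size
#'   (`N <= 14`).
#' @param r_grid Numeric vector of fitness values.
#' @param scheme Initialization scheme name or custom probability vector.
#' @return Data frame with columns `r`, `rho`, `rho_ref`, `difference`.
#' @export
fixation_difference_curve <- function(g, reference, r_grid,
                                      scheme = "temperature") {
  if (g$N != reference$N) stop("graphs must have the same number of vertices")
  rho <- exact_fixation(g, r_grid, scheme)
  rho_ref <- exact_fixation(reference, r_grid, scheme)
  data.frame(r = r_grid, rho = rho, rho_ref = rho_ref,
             difference = rho - rho_ref)
}
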