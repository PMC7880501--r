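#' Weighted evolutionary graph
#'
#' Construct an `evograph` object: a population structure for the Birth-death
#' Moran process. Each of the `N` vertices hosts one haploid individual; the
#' edge weight `w[i, j] >= 0` governs how likely an offspring born at `i` is
#' to replace the occupant of `j`.
#'
#' @param w Square numeric matrix of nonnegative finite edge weights. Row `i`
#'   holds the out-weights of vertex `i`. Self-loops (`w[i, i] > 0`) are
#'   representable, although none of the family constructors produce them.
#' @param directed Logical; if `NULL` (default), inferred from the symmetry
#'   of `w`. Supplying `directed = FALSE` for an asymmetric matrix is an
#'   error.
#'
#' @return An object of class `evograph` with fields `w` (weight matrix),
#'   `N` (vertex count) and `directed`.
#' @seealso [step_probabilities()], [temperatures()], [is_strongly_connected()]
#' @export
evograph <- function(w, directed = NULL) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) stop("weight matrix must be square")
  if (nrow(w) < 2) stop("a population needs at least 2 vertices")
  storage.mode(w) <- "double"
  if (anyNA(w) || any(!is.finite(w))) stop("all edge weights must be finite")
  if (any(w < 0)) stop("edge weights must be nonnegative")
  sym <- isTRUE(all.equal(w, t(w), tolerance = 0, check.attributes = FALSE))
  if (is.null(directed)) {
    directed <- !sym
  } else if (!directed && !sym) {
    stop("matrix is not symmetric; cannot mark graph as undirected")
  }
  dimnames(w) <- NULL
  structure(list(w = w, N = nrow(w), directed = directed),
            class = "evograph")
}

#' @export
print.evograph <- function(x, ...) {
  kind <- if (x$directed) "directed" else "undirected"
  wts <- if (is_unweighted(x)) "unweighted" else "weighted"
  cat(sprintf("<evograph: %d vertices, %s, %s, %d edges>\n",
              x$N, kind, wts, n_edges(x)))
  invisible(x)
}

n_edges <- function(g) {
  nz <- g$w > 0
  if (g$directed) sum(nz) else (sum(nz) + sum(diag(nz))) / 2L
}

#' Test whether all edge weights are 0 or 1
#'
#' @param g An [evograph()].
#' @return Logical flag.
#' @export
is_unweighted <- function(g) {
  all(g$w == 0 | g$w == 1)
}

#' Weighted out-degrees
#'
#' `w_i = sum_j w_ij`, the total out-weight of each vertex.
#'
#' @param g An [evograph()].
#' @return Numeric vector of length `N`.
#' @export
weighted_degrees <- function(g) {
  rowSums(g$w)
}

#' Random-walk step probabilities
#'
#' The offspring of vertex `i` replaces vertex `j` with probability
#' `p_ij = w_ij / w_i`. Rows of the returned matrix sum to one.
#'
#' @param g An [evograph()].
#' @return `N x N` row-stochastic matrix.
#' @export
step_probabilities <- function(g) {
  wd <- weighted_degrees(g)
  if (any(wd <= 0)) {
    stop("vertex with zero out-degree: random walk undefined; graph invalid")
  }
  g$w / wd
}

#' Vertex temperatures
#'
#' `T_i = sum_j p_ji`: the expected number of times vertex `i` is replaced
#' per time step of the Birth-death process, under neutrality. Temperatures
#' always sum to the population size `N`.
#'
#' @param g An [evograph()].
#' @return Numeric vector of length `N`.
#' @export
temperatures <- function(g) {
  colSums(step_probabilities(g))
}

#' Strong connectivity
#'
#' Every vertex must reach every other along positive-weight directed edges
#' for the fixation problem to be well posed. For undirected graphs this is
#' ordinary connectivity.
#'
#' @param g An [evograph()].
#' @return Logical flag.
#' @export
is_strongly_connected <- function(g) {
  adj <- g$w > 0
  reaches_all(adj) && reaches_all(t(adj))
}

# BFS from vertex 1 over a logical adjacency matrix
reaches_all <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Isothermality test
#'
#' A graph is isothermal when every temperature equals one; the fixation
#' probability then matches the well-mixed Moran formula for every mutant
#' fitness (Isothermal Theorem). For unweighted undirected graphs the test is
#' structural -- isothermal if and only if regular -- so survey counts are
#' exact. Weighted graphs are tested numerically.
#'
#' @param g An [evograph()].
#' @param tol Absolute tolerance on `|T_i - 1|` for weighted graphs.
#' @return Logical flag.
#' @export
is_isothermal <- function(g, tol = 1e-12) {
  if (is_unweighted(g) && !g$directed) {
    deg <- rowSums(g$w)
    return(all(deg == deg[1L]))
  }
  max(abs(temperatures(g) - 1)) <= tol
}

# automorphism generators attached by family constructors (list of
# permutation vectors); used by the orbit-reduced coalescence solver
aut_generators <- function(g) {
  attr(g, "aut_generators")
}

`aut_generators<-` <- function(g, value) {
  attr(g, "aut_generators") <- value
  g
}

#' Convert to an igraph object
#'
#' Convenience bridge for plotting or for igraph's structural algorithms.
#' Weights are carried in the `weight` edge attribute.
#'
#' @param g An [evograph()].
#' @return An `igraph` graph.
#' @export
as_igraph <- function(g) {
  mode <- if (g$directed) "directed" else "undirected"
  igraph::graph_from_adjacency_matrix(g$w, mode = mode, weighted = TRUE,
                                      diag = any(diag(g$w) > 0))
}
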