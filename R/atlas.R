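## Enumeration of small simple connected graphs, and seeded random fixtures.

.evograph_cache <- new.env(parent = emptyenv())

#' All connected simple graphs of a given size
#'
#' Enumerates the non-isomorphic connected simple (unweighted, undirected,
#' loop-free) graphs on `N <= 7` vertices from igraph's built-in graph
#' atlas. Counts per size are 1, 2, 6, 21, 112, 853 for N = 2..7.
#' Results are memoized within the session.
#'
#' @param N Number of vertices (2..7).
#' @return List of [evograph()] objects.
#' @export
atlas_graphs <- function(N) {
  N <- check_count(N, "N", 2)
  if (N > 7) stop("the built-in atlas covers sizes up to 7; supply a graph6 ",
                  "file from a standard generator for larger sizes")
  key <- paste0("atlas", N)
  if (!is.null(.evograph_cache[[key]])) return(.evograph_cache[[key]])
  out <- list()
  for (i in 0:1252) {
    ig <- igraph::graph_from_atlas(i)
    if (igraph::vcount(ig) != N || !igraph::is_connected(ig)) next
    w <- as.matrix(igraph::as_adjacency_matrix(ig, sparse = FALSE))
    out[[length(out) + 1L]] <- evograph(w, directed = FALSE)
  }
  .evograph_cache[[key]] <- out
  out
}

#' Seeded random strongly connected graph
#'
#' Fixture generator: draws Erdos-Renyi-type graphs until one is strongly
#' connected (bounded attempts). Identical `seed` gives identical output.
#'
#' @param N Number of vertices (>= 2).
#' @param p Edge probability (default 0.5).
#' @param directed Draw a digraph? Default `FALSE`.
#' @param weights `"unit"` for an unweighted graph or `"uniform"` for i.i.d.
#'   Uniform(0.1, 2) weights on the present edges.
#' @param seed Integer seed (required, for reproducibility).
#' @return An [evograph()].
#' @export
random_connected_graph <- function(N, p = 0.5, directed = FALSE,
                                   weights = c("unit", "uniform"),
                                   seed) {
  N <- check_count(N, "N", 2)
  weights <- match.arg(weights)
  if (missing(seed)) stop("'seed' is required")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (attempt in 1:1000) {
    w <- matrix(as.numeric(stats::runif(N * N) < p), N, N)
    diag(w) <- 0
    if (!directed) w[lower.tri(w)] <- t(w)[lower.tri(w)]
    if (weights == "uniform") {
      u <- matrix(stats::runif(N * N, 0.1, 2), N, N)
      if (!directed) u[lower.tri(u)] <- t(u)[lower.tri(u)]
      w <- w * u
    }
    g <- evograph(w, directed = directed)
    if (is_strongly_connected(g)) return(g)
  }
  stop("failed to draw a strongly connected graph in 1000 attempts")
}
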