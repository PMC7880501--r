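## Named graph families. Each constructor returns an evograph and, where the
## automorphism group is known, attaches a generating set of vertex
## permutations used by the orbit-reduced coalescence solver.

perm_id <- function(N) seq_len(N)

perm_swap <- function(N, a, b) {
  p <- perm_id(N)
  p[c(a, b)] <- c(b, a)
  p
}

# cyclic shift among the listed vertices (in order)
perm_cycle <- function(N, verts) {
  p <- perm_id(N)
  if (length(verts) >= 2) p[verts] <- verts[c(seq_along(verts)[-1], 1L)]
  p
}

# generators of the symmetric group on `verts` (identity-free list)
sym_group_gens <- function(N, verts) {
  gens <- list()
  if (length(verts) >= 2) gens <- c(gens, list(perm_swap(N, verts[1], verts[2])))
  if (length(verts) >= 3) gens <- c(gens, list(perm_cycle(N, verts)))
  gens
}

check_count <- function(x, name, min) {
  if (length(x) != 1 || !is.finite(x) || x != round(x) || x < min) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

#' Complete graph
#'
#' Unit-weight clique on `N` vertices: the well-mixed population.
#'
#' @param N Number of vertices (>= 2).
#' @return An [evograph()].
#' @export
complete_graph <- function(N) {
  N <- check_count(N, "N", 2)
  w <- matrix(1, N, N)
  diag(w) <- 0
  g <- evograph(w, directed = FALSE)
  aut_generators(g) <- sym_group_gens(N, seq_len(N))
  g
}

#' Cycle graph
#'
#' Unit-weight ring on `N` vertices (a regular, hence isothermal, graph).
#'
#' @param N Number of vertices (>= 3).
#' @return An [evograph()].
#' @export
cycle_graph <- function(N) {
  N <- check_count(N, "N", 3)
  w <- matrix(0, N, N)
  idx <- cbind(seq_len(N), c(seq_len(N)[-1], 1L))
  w[idx] <- 1
  w[idx[, 2:1]] <- 1
  g <- evograph(w, directed = FALSE)
  refl <- perm_id(N)
  refl[2:N] <- rev(2:N)
  aut_generators(g) <- list(perm_cycle(N, seq_len(N)), refl)
  g
}

#' Star graph
#'
#' A hub (vertex 1) joined by unit-weight edges to each of `n >= 2` leaves;
#' total size `N = n + 1`.
#'
#' @param n Number of leaves (>= 2).
#' @return An [evograph()].
#' @export
star_graph <- function(n) {
  n <- check_count(n, "n", 2)
  N <- n + 1L
  w <- matrix(0, N, N)
  w[1, 2:N] <- 1
  w[2:N, 1] <- 1
  g <- evograph(w, directed = FALSE)
  aut_generators(g) <- sym_group_gens(N, 2:N)
  g
}

#' Complete bipartite graph
#'
#' Parts of sizes `nA` (vertices `1..nA`) and `nB`; every cross-part pair is
#' joined by a unit-weight edge. The Star is the special case `nA = 1`.
#'
#' @param nA,nB Part sizes (>= 1, `nA + nB >= 2`).
#' @return An [evograph()].
#' @export
complete_bipartite_graph <- function(nA, nB) {
  nA <- check_count(nA, "nA", 1)
  nB <- check_count(nB, "nB", 1)
  N <- nA + nB
  if (N < 2) stop("need at least two vertices")
  w <- matrix(0, N, N)
  w[seq_len(nA), nA + seq_len(nB)] <- 1
  w[nA + seq_len(nB), seq_len(nA)] <- 1
  g <- evograph(w, directed = FALSE)
  aut_generators(g) <- c(sym_group_gens(N, seq_len(nA)),
                         sym_group_gens(N, nA + seq_len(nB)))
  g
}

#' Cartwheel graph
#'
#' An `h`-vertex hub clique and `n` island cliques of `m` vertices each.
#' Island `i` is joined to hub vertex `i` by a single spoke of weight
#' `epsilon`; all other edges have weight 1. Total size `N = n*m + h`.
#' Layout: hub `1..h` (vertices `1..n` carry spokes), island `i` occupies
#' `h + (i-1)*m + 1 .. h + i*m`, with its first vertex attached to the hub.
#'
#' @param n Number of islands (>= 1).
#' @param m Island size (>= 1).
#' @param h Hub size (>= `n`).
#' @param epsilon Spoke weight (> 0). Default 1 gives the unweighted family.
#' @return An [evograph()].
#' @export
cartwheel_graph <- function(n, m, h, epsilon = 1) {
  n <- check_count(n, "n", 1)
  m <- check_count(m, "m", 1)
  h <- check_count(h, "h", n)
  if (!is.finite(epsilon) || epsilon <= 0) stop("'epsilon' must be > 0")
  N <- n * m + h
  if (N < 2) stop("need at least two vertices")
  w <- matrix(0, N, N)
  w[seq_len(h), seq_len(h)] <- 1                       # hub clique
  island <- function(i) h + (i - 1L) * m + seq_len(m)
  for (i in seq_len(n)) {
    v <- island(i)
    w[v, v] <- 1                                       # island clique
    w[i, v[1]] <- epsilon                              # spoke
    w[v[1], i] <- epsilon
  }
  diag(w) <- 0
  g <- evograph(w, directed = FALSE)
  gens <- sym_group_gens(N, h + 1L + seq_len(m - 1L))  # within island 1
  if (h > n) gens <- c(gens, sym_group_gens(N, n + seq_len(h - n)))
  if (n >= 2) {  # swap islands 1 and 2 along with their hub attachments
    p <- perm_swap(N, 1L, 2L)
    p[island(1)] <- island(2)
    p[island(2)] <- island(1)
    gens <- c(gens, list(p))
  }
  if (n >= 3) {  # cycle all islands with their hub attachments
    p <- perm_cycle(N, seq_len(n))
    for (i in seq_len(n)) p[island(i)] <- island(if (i == n) 1L else i + 1L)
    gens <- c(gens, list(p))
  }
  aut_generators(g) <- gens
  g
}

#' Detour graph
#'
#' A complete graph on `c` vertices with the edge between vertices 1 and 2
#' replaced by a path through `d` interior vertices (`c+1 .. c+d`). Total
#' size `N = c + d`. All weights are 1.
#'
#' @param c Clique size (>= 3).
#' @param d Number of interior path vertices (>= 1).
#' @return An [evograph()].
#' @export
detour_graph <- function(c, d) {
  c <- check_count(c, "c", 3)
  d <- check_count(d, "d", 1)
  N <- c + d
  w <- matrix(0, N, N)
  w[seq_len(c), seq_len(c)] <- 1
  diag(w) <- 0
  w[1, 2] <- w[2, 1] <- 0                   # removed clique edge
  path <- c + seq_len(d)
  ends <- c(1L, path, 2L)
  for (k in seq_len(length(ends) - 1L)) {
    w[ends[k], ends[k + 1L]] <- 1
    w[ends[k + 1L], ends[k]] <- 1
  }
  g <- evograph(w, directed = FALSE)
  gens <- sym_group_gens(N, 2L + seq_len(c - 2L))  # interior clique vertices
  refl <- perm_swap(N, 1L, 2L)                     # reflection through the path
  refl[path] <- rev(path)
  aut_generators(g) <- c(gens, list(refl))
  g
}

#' Fan graph
#'
#' A hub vertex (vertex 1) attached by weight-`epsilon` edges to every vertex
#' of `n >= 2` blades, each blade a unit-weight clique of `m >= 2` vertices.
#' Total size `N = n*m + 1`. The graph is isothermal at
#' `epsilon = (m - 1) / (m*n - 1)`.
#'
#' @param n Number of blades (>= 2).
#' @param m Blade size (>= 2).
#' @param epsilon Hub-blade edge weight (> 0).
#' @return An [evograph()].
#' @export
fan_graph <- function(n, m, epsilon) {
  n <- check_count(n, "n", 2)
  m <- check_count(m, "m", 2)
  if (!is.finite(epsilon) || epsilon <= 0) stop("'epsilon' must be > 0")
  N <- n * m + 1L
  w <- matrix(0, N, N)
  blade <- function(i) 1L + (i - 1L) * m + seq_len(m)
  for (i in seq_len(n)) {
    v <- blade(i)
    w[v, v] <- 1
    w[1, v] <- epsilon
    w[v, 1] <- epsilon
  }
  diag(w) <- 0
  g <- evograph(w, directed = FALSE)
  gens <- sym_group_gens(N, blade(1))
  p <- perm_id(N)                       # swap blades 1 and 2
  p[blade(1)] <- blade(2)
  p[blade(2)] <- blade(1)
  gens <- c(gens, list(p))
  if (n >= 3) {
    p <- perm_id(N)
    for (i in seq_len(n)) p[blade(i)] <- blade(if (i == n) 1L else i + 1L)
    gens <- c(gens, list(p))
  }
  aut_generators(g) <- gens
  g
}

#' Lollipop graph
#'
#' A clique of `c` vertices with a path of `d` vertices hanging from clique
#' vertex 1. Among unweighted graphs these have extremal random-walk hitting
#' and commute times, and they emerge as strong suppressors of weak selection
#' under uniform initialization.
#'
#' @param c Clique size (>= 3).
#' @param d Tail length (>= 1).
#' @return An [evograph()].
#' @export
lollipop_graph <- function(c, d) {
  c <- check_count(c, "c", 3)
  d <- check_count(d, "d", 1)
  N <- c + d
  w <- matrix(0, N, N)
  w[seq_len(c), seq_len(c)] <- 1
  diag(w) <- 0
  chain <- c(1L, c + seq_len(d))
  for (k in seq_len(d)) {
    w[chain[k], chain[k + 1L]] <- 1
    w[chain[k + 1L], chain[k]] <- 1
  }
  g <- evograph(w, directed = FALSE)
  aut_generators(g) <- sym_group_gens(N, 1L + seq_len(c - 1L))
  g
}

#' Balloon graph
#'
#' A clique of `c` vertices without the edge between vertices 1 and 2, plus a
#' tail path of `d` vertices whose two ends attach to vertices 1 and 2. With
#' the attachment vertices non-adjacent (the default) this is structurally a
#' Detour graph read with the path as a "tail"; set
#' `attached_adjacent = TRUE` to keep the clique edge between the attachment
#' vertices, which yields a genuinely different graph.
#'
#' @param c Clique size (>= 3).
#' @param d Tail length (>= 1).
#' @param attached_adjacent Keep the edge between the two attachment
#'   vertices? Default `FALSE`.
#' @return An [evograph()].
#' @export
balloon_graph <- function(c, d, attached_adjacent = FALSE) {
  g <- detour_graph(c, d)
  if (attached_adjacent) {
    g$w[1, 2] <- g$w[2, 1] <- 1
    g2 <- evograph(g$w, directed = FALSE)
    aut_generators(g2) <- aut_generators(g)
    g <- g2
  }
  g
}

#' Balloon-star graph
#'
#' A clique of `c` vertices, a tail path of `d` vertices from clique vertex
#' 1, with the terminal path vertex acting as the hub of a star with `s`
#' leaves. Total size `N = c + d + s`.
#'
#' @param c Clique size (>= 3).
#' @param d Tail length (>= 1).
#' @param s Number of terminal star leaves (>= 1).
#' @return An [evograph()].
#' @export
balloon_star_graph <- function(c, d, s) {
  c <- check_count(c, "c", 3)
  d <- check_count(d, "d", 1)
  s <- check_count(s, "s", 1)
  N <- c + d + s
  w <- matrix(0, N, N)
  w[seq_len(c), seq_len(c)] <- 1
  diag(w) <- 0
  chain <- c(1L, c + seq_len(d))
  for (k in seq_len(d)) {
    w[chain[k], chain[k + 1L]] <- 1
    w[chain[k + 1L], chain[k]] <- 1
  }
  hub <- c + d
  leaves <- c + d + seq_len(s)
  w[hub, leaves] <- 1
  w[leaves, hub] <- 1
  g <- evograph(w, directed = FALSE)
  aut_generators(g) <- c(sym_group_gens(N, 1L + seq_len(c - 1L)),
                         sym_group_gens(N, leaves))
  g
}

#' Build a family graph by name
#'
#' Dispatch table over the named constructors, convenient for scripted and
#' command-line use.
#'
#' @param name One of `"complete"`, `"cycle"`, `"star"`,
#'   `"complete_bipartite"`, `"cartwheel"`, `"detour"`, `"fan"`,
#'   `"lollipop"`, `"balloon"`, `"balloon_star"`.
#' @param ... Parameters passed to the constructor.
#' @return An [evograph()].
#' @export
make_family <- function(name, ...) {
  ctor <- switch(match.arg(name, c("complete", "cycle", "star",
                                   "complete_bipartite", "cartwheel",
                                   "detour", "fan", "lollipop", "balloon",
                                   "balloon_star")),
    complete = complete_graph, cycle = cycle_graph, star = star_graph,
    complete_bipartite = complete_bipartite_graph,
    cartwheel = cartwheel_graph, detour = detour_graph, fan = fan_graph,
    lollipop = lollipop_graph, balloon = balloon_graph,
    balloon_star = balloon_star_graph)
  ctor(...)
}
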