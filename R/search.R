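## Extremal-structure search: a truncation-selection genetic algorithm over
## simple unweighted graphs, and deterministic scans over the Detour and
## Cartwheel families.

#' Genetic-algorithm search for extremal graphs
#'
#' Evolves an ensemble of simple connected unweighted graphs toward an
#' extreme of `rho'` or `rho'/rho0`. Truncation selection keeps the best
#' `keep` graphs each generation; `elite` of them are copied unchanged
#' (so the best score is non-decreasing); offspring are formed by per-pair
#' uniform crossover of two surviving parents' adjacency indicators,
#' followed by independent edge toggling with probability `mut_prob`, and
#' repaired to connectivity by inserting random edges between components.
#' Scores are cached by canonical form. Reproducible for a fixed seed.
#'
#' @param objective `"max_rho_prime"`, `"min_rho_prime"`, `"max_ratio"`, or
#'   `"min_ratio"`.
#' @param scheme `"temperature"` or `"uniform"`.
#' @param N Graph size.
#' @param pop Population size (default 100).
#' @param keep Survivors per generation (default 20).
#' @param elite Elite count carried unchanged (default 5).
#' @param mut_prob Per-pair mutation probability; default `2 / (N (N-1))`,
#'   i.e. two expected toggles per offspring.
#' @param generations Number of generations (default 200).
#' @param seed Integer seed (required).
#' @return List with `best` (an [evograph()]), `best_score`, `elite`
#'   (list of graph/score pairs), and `trajectory` (best score per
#'   generation).
#' @export
genetic_search <- function(objective = c("max_rho_prime", "min_rho_prime",
                                         "max_ratio", "min_ratio"),
                           scheme = c("temperature", "uniform"),
                           N, pop = 100, keep = 20, elite = 5,
                           mut_prob = NULL, generations = 200, seed) {
  objective <- match.arg(objective)
  scheme <- match.arg(scheme)
  N <- check_count(N, "N", 3)
  if (missing(seed)) stop("'seed' is required")
  if (keep > pop || elite > keep) stop("need pop >= keep >= elite")
  if (is.null(mut_prob)) mut_prob <- 2 / (N * (N - 1))
  if (mut_prob < 0 || mut_prob > 1) stop("'mut_prob' must be in [0, 1]")
  maximize <- grepl("^max", objective)
  M <- N * (N - 1L) / 2L
  up <- which(upper.tri(matrix(0, N, N)))

  to_graph <- function(bits) {
    w <- matrix(0, N, N)
    w[up] <- bits
    evograph(w + t(w), directed = FALSE)
  }
  repair <- function(bits) {
    repeat {
      g <- to_graph(bits)
      comp <- igraph::components(as_igraph(g))
      if (comp$no == 1L) return(bits)
      # join two components with a random edge
      a <- sample(which(comp$membership == 1L), 1)
      b <- sample(which(comp$membership != 1L), 1)
      w <- matrix(0, N, N)
      w[up] <- seq_len(M)
      bits[w[min(a, b), max(a, b)]] <- 1
    }
  }
  cache <- new.env(parent = emptyenv())
  score <- function(bits) {
    g <- to_graph(bits)
    ig <- as_igraph(g)
    key <- format_graph6(to_graph_canonical(ig, N))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    ws <- weak_selection(g, scheme)
    val <- if (grepl("rho_prime", objective)) ws$rho_prime else ws$ratio
    cache[[key]] <- val
    val
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  popn <- lapply(seq_len(pop), function(i) {
    repair(as.integer(stats::runif(M) < 0.5))
  })
  scores <- vapply(popn, score, 0)
  trajectory <- numeric(generations)
  for (gen in seq_len(generations)) {
    ord <- order(if (maximize) -scores else scores)
    popn <- popn[ord]
    scores <- scores[ord]
    survivors <- popn[seq_len(keep)]
    children <- lapply(seq_len(pop - elite), function(i) {
      par <- sample.int(keep, 2, replace = TRUE)
      pick <- stats::runif(M) < 0.5
      bits <- ifelse(pick, survivors[[par[1]]], survivors[[par[2]]])
      flip <- stats::runif(M) < mut_prob
      bits[flip] <- 1L - bits[flip]
      repair(bits)
    })
    popn <- c(popn[seq_len(elite)], children)
    scores <- c(scores[seq_len(elite)], vapply(children, score, 0))
    trajectory[gen] <- if (maximize) max(scores) else min(scores)
  }
  ord <- order(if (maximize) -scores else scores)
  list(best = to_graph(popn[[ord[1]]]), best_score = scores[ord[1]],
       elite = lapply(ord[seq_len(elite)], function(i) {
         list(graph = to_graph(popn[[i]]), score = scores[i])
       }),
       trajectory = trajectory)
}

# canonical relabeling for the score cache
to_graph_canonical <- function(ig, N) {
  perm <- igraph::canonical_permutation(ig)$labeling
  ig2 <- igraph::permute(ig, perm)
  evograph(as.matrix(igraph::as_adjacency_matrix(ig2, sparse = FALSE)),
           directed = FALSE)
}

#' Detour parameter scan
#'
#' For every admissible number of path vertices `d`, builds the Detour
#' `D_{N-d, d}` and computes the weak-selection summary. The ratio
#' `rho'/rho0` is minimized at an intermediate `d` that grows sublinearly
#' with `N`; these graphs are the strongest known relative suppressors
#' under temperature initialization.
#'
#' @param N Total size (>= 4).
#' @param scheme `"temperature"` or `"uniform"`.
#' @return List with `table` (data frame over `d` with `rho0`, `rho_prime`,
#'   `ratio`) and `d_min` (the `d` minimizing the ratio).
#' @export
detour_scan <- function(N, scheme = "temperature") {
  N <- check_count(N, "N", 4)
  ds <- seq_len(N - 3L)
  rows <- lapply(ds, function(d) {
    ws <- weak_selection(detour_graph(N - d, d), scheme)
    data.frame(d = d, c = N - d, rho0 = ws$rho0, rho_prime = ws$rho_prime,
               ratio = ws$ratio)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, d_min = tab$d[which.min(tab$ratio)],
       min_ratio = min(tab$ratio))
}

#' Cartwheel parameter scan
#'
#' Exhaustively scans all `(n, m, h)` with `n m + h = N` and `h >= n >= 1`,
#' `m >= 1`, and returns the Cartwheel maximizing `rho'` under temperature
#' initialization at spoke weight `epsilon` (default 1, the unweighted
#' family).
#'
#' @param N Total size (>= 5).
#' @param epsilon Spoke weight (default 1).
#' @return List with `table` (data frame over parameter triples) and
#'   `best` (row with maximal `rho_prime`).
#' @export
cartwheel_scan <- function(N, epsilon = 1) {
  N <- check_count(N, "N", 5)
  rows <- list()
  for (m in seq_len(N - 1L)) {
    for (n in seq_len((N - 1L) %/% m)) {
      h <- N - n * m
      if (h < n || h < 1L) next
      ws <- weak_selection(cartwheel_graph(n, m, h, epsilon), "temperature")
      rows[[length(rows) + 1L]] <-
        data.frame(n = n, m = m, h = h, rho0 = ws$rho0,
                   rho_prime = ws$rho_prime, ratio = ws$ratio)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$rho_prime, tab$n, tab$m), ]
  rownames(tab) <- NULL
  list(table = tab, best = tab[1, ])
}
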