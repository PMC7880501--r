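## Amplifier/suppressor taxonomy and exhaustive surveys.
##
## A graph is an absolute amplifier of weak selection when
## rho' > (N-1)/(2N) (the isothermal value) and an absolute suppressor when
## rho' < (N-1)/(2N). It is a relative amplifier when rho'/rho0 > (N-1)/2
## and a relative suppressor otherwise; the ratio governs how many selected
## versus neutral substitutions accrue. Under temperature initialization
## rho0 <= 1/N, so rho'/rho0 >= N rho' and "absolute amplifier + relative
## suppressor" cannot occur. Under uniform initialization rho0 = 1/N for
## every graph and the two notions coincide.

CLASS_LEVELS <- c("isothermal",
                  "absolute and relative amplifier",
                  "absolute suppressor, relative amplifier",
                  "absolute and relative suppressor",
                  "amplifier", "suppressor")

#' Classify one graph
#'
#' Isothermal graphs are recognized structurally first (regularity, for
#' unweighted undirected input), so the isothermal count of a survey is
#' exact. Other graphs are classified by comparing `rho'` with
#' `(N-1)/(2N)` and `rho'/rho0` with `(N-1)/2`; the smaller of the two
#' float margins is reported so callers can detect borderline cases.
#'
#' @param g A strongly connected [evograph()].
#' @param scheme `"temperature"` or `"uniform"`.
#' @param method Solver passed to [weak_selection()].
#' @return List with `N`, `scheme`, `rho0`, `rho_prime`, `ratio`,
#'   `classification` (one of the fixed labels) and `margin`.
#' @export
classify_graph <- function(g, scheme = c("temperature", "uniform"),
                           method = "auto") {
  scheme <- match.arg(scheme)
  ws <- weak_selection(g, scheme, method = method)
  iso <- is_isothermal(g)
  abs_thr <- (ws$N - 1) / (2 * ws$N)
  rel_thr <- (ws$N - 1) / 2
  m_abs <- ws$rho_prime - abs_thr
  m_rel <- ws$ratio - rel_thr
  cls <- if (iso) {
    "isothermal"
  } else if (scheme == "uniform") {
    if (m_abs > 0) "amplifier" else "suppressor"
  } else if (m_abs > 0 && m_rel > 0) {
    "absolute and relative amplifier"
  } else if (m_abs < 0 && m_rel > 0) {
    "absolute suppressor, relative amplifier"
  } else {
    "absolute and relative suppressor"
  }
  margin <- if (iso) NA_real_ else min(abs(m_abs), abs(m_rel))
  c(ws, list(classification = cls, margin = margin))
}

#' Survey a set of graphs
#'
#' Classifies every graph in a stream (a list of [evograph()] objects, or a
#' path to a graph6 file from a standard generator) and tabulates the
#' counts, mirroring the exhaustive small-graph analyses. Non-simple or
#' disconnected graphs are rejected and counted. Any non-isothermal graph
#' whose classification margin falls below `borderline` stops the survey:
#' such counts could not be trusted from floating point alone. No graph in
#' the complete size-<=7 sets comes near this margin.
#'
#' @param graphs List of [evograph()] objects or a graph6 file path.
#' @param scheme `"temperature"` or `"uniform"`.
#' @param borderline Margin below which classification is refused.
#' @return List with `counts` (named integer vector over the labels in use),
#'   `total`, `rejected`, and `N`.
#' @export
survey_graphs <- function(graphs, scheme = c("temperature", "uniform"),
                          borderline = 1e-9) {
  scheme <- match.arg(scheme)
  if (is.character(graphs)) graphs <- read_graph6_file(graphs)
  labels <- if (scheme == "temperature") CLASS_LEVELS[1:4] else
    c("isothermal", CLASS_LEVELS[5:6])
  counts <- stats::setNames(integer(length(labels)), labels)
  rejected <- 0L
  N <- NA_integer_
  for (g in graphs) {
    simple <- is_unweighted(g) && !g$directed && all(diag(g$w) == 0)
    if (!simple || !is_strongly_connected(g)) {
      rejected <- rejected + 1L
      next
    }
    N <- g$N
    cl <- classify_graph(g, scheme)
    if (!is.na(cl$margin) && cl$margin < borderline) {
      stop(sprintf("borderline classification (margin %.3g) for graph %s",
                   cl$margin, format_graph6(g)))
    }
    counts[cl$classification] <- counts[cl$classification] + 1L
  }
  list(counts = counts, total = sum(counts), rejected = rejected, N = N)
}

#' Survey table over sizes
#'
#' Runs [survey_graphs()] on the complete atlas of connected simple graphs
#' for each requested size and assembles a data frame shaped like the
#' published classification tables (one column per size, one row per
#' classification plus a total row).
#'
#' @param sizes Integer vector of sizes, each between 3 and 7.
#' @param scheme `"temperature"` or `"uniform"`.
#' @return A data frame; rownames are the classification labels.
#' @export
survey_table <- function(sizes = 3:7, scheme = c("temperature", "uniform")) {
  scheme <- match.arg(scheme)
  cols <- lapply(sizes, function(N) {
    sv <- survey_graphs(atlas_graphs(N), scheme)
    c(sv$counts, Total = sv$total)
  })
  out <- as.data.frame(do.call(cbind, cols))
  names(out) <- paste0("N", sizes)
  out
}

#' Extremal graphs of a stream
#'
#' Ranks the graphs of a stream by `rho'` or by `rho'/rho0` and returns the
#' top `k`, with deterministic tie-breaking by graph6 encoding.
#'
#' @param graphs List of [evograph()] objects or a graph6 file path.
#' @param scheme `"temperature"` or `"uniform"`.
#' @param objective One of `"max_rho_prime"`, `"min_rho_prime"`,
#'   `"max_ratio"`, `"min_ratio"`.
#' @param k Number of graphs to return.
#' @return List of `k` lists with elements `graph`, `value`, `summary`.
#' @export
extremal_graphs <- function(graphs, scheme = c("temperature", "uniform"),
                            objective = c("max_rho_prime", "min_rho_prime",
                                          "max_ratio", "min_ratio"),
                            k = 1) {
  scheme <- match.arg(scheme)
  objective <- match.arg(objective)
  if (is.character(graphs)) graphs <- read_graph6_file(graphs)
  if (!length(graphs)) stop("empty graph stream")
  res <- lapply(graphs, function(g) {
    ws <- weak_selection(g, scheme)
    val <- if (grepl("rho_prime", objective)) ws$rho_prime else ws$ratio
    list(graph = g, value = val, summary = ws,
         key = format_graph6(g))
  })
  vals <- vapply(res, `[[`, 0, "value")
  keys <- vapply(res, `[[`, "", "key")
  ord <- order(if (grepl("^max", objective)) -vals else vals, keys)
  lapply(res[ord[seq_len(min(k, length(res)))]],
         function(x) x[c("graph", "value", "summary")])
}
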