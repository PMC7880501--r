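# Shared fixtures, built in code.

# directed 3-cycle: 1 -> 2 -> 3 -> 1
directed_triangle <- function() {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 3] <- w[3, 1] <- 1
  evograph(w, directed = TRUE)
}

# mixed pool of seeded random strongly connected graphs
random_graph_pool <- function(n_graphs, sizes = 3:6, seed0 = 1000) {
  lapply(seq_len(n_graphs), function(i) {
    random_connected_graph(
      N = sizes[1 + (i %% length(sizes))],
      directed = i %% 2 == 0,
      weights = if (i %% 3 == 0) "unit" else "uniform",
      seed = seed0 + i)
  })
}

# the unique size-6 absolute-and-relative amplifier under temperature
# initialization (found from the complete size-6 survey; memoized)
bowtie_graph <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      hits <- Filter(function(g) {
        !is_isothermal(g) &&
          classify_graph(g, "temperature")$classification ==
            "absolute and relative amplifier"
      }, atlas_graphs(6))
      stopifnot(length(hits) == 1L)
      cache <<- hits[[1]]
    }
    cache
  }
})
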