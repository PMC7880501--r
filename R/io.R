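## Graph file formats: graph6 (simple unweighted graphs), weighted edge-list
## TSV, and adjacency-matrix CSV. Vertex indices in TSV files are 0-based.

#' Decode a graph6 string
#'
#' graph6 is the compact ASCII encoding used by standard generators of
#' non-isomorphic simple graphs: a size header followed by the upper
#' triangle of the adjacency matrix, read column by column, packed six bits
#' per printable character (offset 63).
#'
#' @param s A single graph6 string (optionally prefixed `">>graph6<<"`).
#' @return An undirected unweighted [evograph()].
#' @export
parse_graph6 <- function(s) {
  if (length(s) != 1 || !is.character(s)) stop("expected a single string")
  s <- sub("^>>graph6<<", "", s)
  bytes <- utf8ToInt(s) - 63L
  if (length(bytes) == 0 || any(bytes < 0 | bytes > 63)) {
    stop("malformed graph6 string")
  }
  if (bytes[1] < 63) {
    n <- bytes[1]
    rest <- bytes[-1]
  } else {
    if (length(bytes) < 4) stop("malformed graph6 header")
    if (bytes[2] == 63) stop("graph6 sizes >= 2^18 not supported")
    n <- bytes[2] * 4096L + bytes[3] * 64L + bytes[4]
    rest <- bytes[-(1:4)]
  }
  if (n < 1) stop("malformed graph6 header")
  nbits <- n * (n - 1) / 2
  if (length(rest) != ceiling(nbits / 6)) stop("graph6 body has wrong length")
  bits <- as.vector(vapply(rest, function(b) bitwAnd(bitwShiftR(b, 5:0), 1L),
                           integer(6)))
  bits <- bits[seq_len(nbits)]
  w <- matrix(0, n, n)
  if (n >= 2) {
    cols <- rep(2:n, times = (2:n) - 1L)
    rows <- unlist(lapply(2:n, function(j) seq_len(j - 1L)))
    w[cbind(rows, cols)] <- bits
    w[cbind(cols, rows)] <- bits
  }
  evograph(w, directed = FALSE)
}

#' Encode a graph as a graph6 string
#'
#' @param g An undirected unweighted [evograph()] without self-loops.
#' @return A single graph6 string.
#' @export
format_graph6 <- function(g) {
  if (g$directed) stop("graph6 encodes undirected graphs only")
  if (!is_unweighted(g)) stop("graph6 encodes unweighted graphs only")
  if (any(diag(g$w) != 0)) stop("graph6 does not encode self-loops")
  n <- g$N
  header <- if (n <= 62) {
    intToUtf8(n + 63L)
  } else if (n < 2^18) {
    intToUtf8(c(126L, 63L + c(n %/% 4096L, (n %/% 64L) %% 64L, n %% 64L)))
  } else {
    stop("graph6 sizes >= 2^18 not supported")
  }
  cols <- rep(2:n, times = (2:n) - 1L)
  rows <- unlist(lapply(2:n, function(j) seq_len(j - 1L)))
  bits <- as.integer(g$w[cbind(rows, cols)] > 0)
  pad <- (-length(bits)) %% 6
  bits <- c(bits, integer(pad))
  groups <- matrix(bits, nrow = 6)
  vals <- as.integer(2^(5:0) %*% groups)
  paste0(header, intToUtf8(vals + 63L))
}

#' Read graphs from a graph6 file
#'
#' @param path File with one graph6 string per line.
#' @return List of [evograph()] objects.
#' @export
read_graph6_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, parse_graph6)
}

#' Read a graph from a file
#'
#' Supported formats: `"graph6"` (first graph of the file), `"edgelist"`
#' (TSV columns `src dst weight`, 0-based vertices, with an optional
#' `# directed: true|false` header line; undirected inputs are symmetrized),
#' and `"adjacency"` (N x N CSV, row i = out-weights of vertex i, no header).
#'
#' @param path Input file path.
#' @param format One of `"graph6"`, `"edgelist"`, `"adjacency"`.
#' @return An [evograph()].
#' @export
read_graph <- function(path, format = c("graph6", "edgelist", "adjacency")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read graph: no such file: ", path)
  switch(format,
    graph6 = read_graph6_file(path)[[1]],
    edgelist = read_edgelist(path),
    adjacency = read_adjacency(path))
}

read_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  directed <- FALSE
  hdr <- grep("^#", lines, value = TRUE)
  m <- regmatches(hdr, regexpr("directed:\\s*(true|false)", hdr, ignore.case = TRUE))
  if (length(m)) directed <- grepl("true", m[[1]], ignore.case = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body)) stop("edge list is empty")
  df <- utils::read.table(text = body, col.names = c("src", "dst", "weight"))
  if (any(df$weight < 0)) stop("negative weight in edge list")
  if (any(df$src < 0 | df$dst < 0)) stop("vertex indices must be >= 0")
  n <- max(df$src, df$dst) + 1L
  w <- matrix(0, n, n)
  w[cbind(df$src + 1L, df$dst + 1L)] <- df$weight
  if (!directed) w[cbind(df$dst + 1L, df$src + 1L)] <- df$weight
  evograph(w, directed = directed)
}

read_adjacency <- function(path) {
  w <- as.matrix(utils::read.csv(path, header = FALSE))
  if (nrow(w) != ncol(w)) stop("adjacency CSV must be square")
  evograph(w)
}

#' Write a graph to a file
#'
#' Formats as in [read_graph()]; `write_graph(g, path, fmt)` then
#' `read_graph(path, fmt)` reproduces the weight matrix exactly.
#'
#' @param g An [evograph()].
#' @param path Output file path.
#' @param format One of `"graph6"`, `"edgelist"`, `"adjacency"`.
#' @return `path`, invisibly.
#' @export
write_graph <- function(g, path, format = c("graph6", "edgelist", "adjacency")) {
  format <- match.arg(format)
  switch(format,
    graph6 = writeLines(format_graph6(g), path),
    edgelist = {
      nz <- which(g$w > 0, arr.ind = TRUE)
      if (!g$directed) nz <- nz[nz[, 1] <= nz[, 2], , drop = FALSE]
      lines <- c(sprintf("# directed: %s", tolower(g$directed)),
                 sprintf("%d\t%d\t%.17g", nz[, 1] - 1L, nz[, 2] - 1L,
                         g$w[nz]))
      writeLines(lines, path)
    },
    adjacency = {
      rows <- apply(g$w, 1, function(x) paste(sprintf("%.17g", x),
                                              collapse = ","))
      writeLines(rows, path)
    })
  invisible(path)
}
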