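#' Read and write graphs
#'
#' Two plain-text formats are supported. `"edgelist"`: one whitespace
#' separated label pair per line, `#` starts a comment, and an optional
#' first line `n=<count>` fixes the vertex count. `"graphml"`: undirected
#' GraphML with node ids equal to the vertex labels. Both readers reject
#' directed edges and edge weights, because every descriptor in this
#' package is defined on unweighted undirected graphs; nothing is silently
#' dropped.
#'
#' @param path File path.
#' @param format One of `"edgelist"`, `"graphml"`.
#' @param g A validated graph (see [buildGraph()]).
#' @return `readGraph` returns a validated graph with labels `1..n`;
#'   `writeGraph` returns `path` invisibly. A write-then-read round trip
#'   reproduces the labelled graph.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeGraph(pathGraph(4), f, format = "edgelist")
#' igraph::ecount(readGraph(f, format = "edgelist"))
#' @name graph_io
NULL

.relabel_contiguous <- function(labels, edges, path) {
  nums <- suppressWarnings(as.numeric(labels))
  if (anyNA(nums)) {
    ord <- order(labels)
  } else {
    ord <- order(nums)
  }
  n <- length(labels)
  map <- integer(n)
  map[ord] <- seq_len(n)
  list(n = n, edges = cbind(map[edges[, 1]], map[edges[, 2]]))
}

.read_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  n_declared <- NA_integer_
  if (length(lines) && grepl("^n=", lines[1L])) {
    n_declared <- suppressWarnings(as.integer(sub("^n=", "", lines[1L])))
    if (is.na(n_declared)) stop(sprintf("malformed vertex-count line: '%s'", lines[1L]))
    lines <- lines[-1L]
  }
  if (!length(lines)) stop("edge list is empty")
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(toks, length, 1L) != 2L
  if (any(bad)) {
    stop(sprintf("malformed edge line: '%s'", lines[which(bad)[1L]]))
  }
  ends <- suppressWarnings(
    matrix(as.numeric(unlist(toks)), ncol = 2, byrow = TRUE))
  if (anyNA(ends)) stop("non-numeric vertex label in edge list")
  if (any(ends[, 1] == ends[, 2])) {
    i <- which(ends[, 1] == ends[, 2])[1L]
    stop(sprintf("edge (%s, %s): self-loops are not allowed",
                 format(ends[i, 1]), format(ends[i, 2])))
  }
  n <- if (is.na(n_declared)) max(ends) else n_declared
  buildGraph(n, ends)
}

.read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::is_directed(g)) stop("directed GraphML graphs are not supported")
  if ("weight" %in% igraph::edge_attr_names(g)) {
    stop("weighted graphs are not supported; remove the edge weight attribute")
  }
  labels <- igraph::vertex_attr(g, "name")
  if (is.null(labels)) labels <- igraph::vertex_attr(g, "id")
  if (is.null(labels)) labels <- as.character(seq_len(igraph::vcount(g)))
  edges <- igraph::as_edgelist(g, names = FALSE)
  rel <- .relabel_contiguous(labels, edges, path)
  buildGraph(rel$n, rel$edges)
}

#' @rdname graph_io
#' @export
readGraph <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  g <- switch(format,
    edgelist = .read_edgelist(path),
    graphml = .read_graphml(path)
  )
  .check_graph(g)
  g
}

#' @rdname graph_io
#' @export
writeGraph <- function(g, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  .check_graph(g, connected = FALSE)
  if (format == "edgelist") {
    el <- igraph::as_edgelist(g, names = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("n=%d", igraph::vcount(g)), con)
    if (nrow(el)) writeLines(paste(el[, 1], el[, 2], sep = "\t"), con)
  } else {
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a directory of graph files as a collection
#'
#' @param dir Directory containing graph files.
#' @param format Passed to [readGraph()].
#' @param pattern Filename filter (default picks the format's extension).
#' @return Named list of graphs; names are file names without extension and
#'   must be unique.
#' @export
readGraphCollection <- function(dir, format = c("edgelist", "graphml"),
                                pattern = NULL) {
  format <- match.arg(format)
  if (is.null(pattern)) {
    pattern <- if (format == "graphml") "\\.graphml$" else "\\.(tsv|txt|edgelist)$"
  }
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (!length(files)) stop(sprintf("no graph files matching '%s' in %s", pattern, dir))
  ids <- sub("\\.[^.]*$", "", basename(files))
  if (anyDuplicated(ids)) stop("duplicate graph identifiers in collection")
  graphs <- lapply(files, readGraph, format = format)
  names(graphs) <- ids
  graphs
}
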