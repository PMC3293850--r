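#' Build a validated graph from an edge list
#'
#' Constructs an undirected simple graph on vertices labelled `1..n`.
#' This is the universal input type of the package: all descriptors operate
#' on igraph objects whose vertices carry contiguous 1-based labels.
#'
#' @param n Number of vertices (labels are `1..n`).
#' @param edges Two-column matrix (or list of length-2 vectors) of vertex
#'   labels, one row per undirected edge.
#' @return An undirected [igraph::igraph] object with vertex names
#'   `"1".."n"`.
#' @examples
#' g <- buildGraph(3, rbind(c(1, 2), c(2, 3)))
#' igraph::ecount(g)
#' @export
buildGraph <- function(n, edges) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("'n' must be a single positive integer")
  }
  if (is.list(edges)) edges <- do.call(rbind, lapply(edges, as.numeric))
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(numeric(0), ncol = 2)
  }
  if (ncol(edges) != 2L) stop("'edges' must have two columns")
  storage.mode(edges) <- "double"
  bad <- edges < 1 | edges > n | edges != round(edges)
  if (any(bad)) {
    i <- which(apply(bad, 1L, any))[1L]
    stop(sprintf("edge (%s, %s): vertex label out of range 1..%d",
                 format(edges[i, 1]), format(edges[i, 2]), n))
  }
  loops <- edges[, 1] == edges[, 2]
  if (any(loops)) {
    i <- which(loops)[1L]
    stop(sprintf("edge (%d, %d): self-loops are not allowed",
                 edges[i, 1], edges[i, 2]))
  }
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop(sprintf("edge (%d, %d): duplicate edge", edges[i, 1], edges[i, 2]))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(edges)))
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

# Entry-point validation shared by all descriptors.  `connected = TRUE` is
# the default because every distance-based quantity assumes finite distances.
.check_graph <- function(g, connected = TRUE) {
  if (!igraph::is_igraph(g)) stop("'g' must be an igraph object")
  if (igraph::is_directed(g)) stop("graph must be undirected")
  if (!igraph::is_simple(g)) stop("graph must be simple (no loops or multi-edges)")
  if (connected && igraph::vcount(g) > 0 && !igraph::is_connected(g)) {
    stop("graph must be connected")
  }
  invisible(g)
}

#' Cyclomatic number
#'
#' For a connected graph, `m - n + 1`: the number of independent cycles.
#' Zero exactly for trees.
#'
#' @param g A connected undirected simple graph.
#' @return Non-negative integer.
#' @export
cyclomatic <- function(g) {
  .check_graph(g)
  igraph::ecount(g) - igraph::vcount(g) + 1L
}

#' All-pairs shortest-path distance matrix
#'
#' BFS hop-count distances between all vertex pairs. Most descriptors accept
#' this matrix through their `dist` argument; computing it once per graph
#' and passing it on avoids repeated BFS sweeps when evaluating many
#' descriptors.
#'
#' @param g A connected undirected simple graph.
#' @return An `n x n` symmetric integer-valued matrix with zero diagonal.
#' @examples
#' dm <- distanceMatrix(pathGraph(7))
#' max(dm)  # diameter
#' @export
distanceMatrix <- function(g) {
  .check_graph(g)
  d <- igraph::distances(g, algorithm = "unweighted")
  dimnames(d) <- NULL
  d
}

#' Distance-matrix summary statistics
#'
#' Derives from a distance matrix the per-vertex distance degrees
#' `s_i = sum_j d_ij`, the diameter `rho`, and the distance-frequency
#' spectrum `g_k` (number of unordered vertex pairs at distance `k`,
#' `k = 1..rho`). These feed most distance-based descriptors.
#'
#' @param dist A distance matrix as returned by [distanceMatrix()].
#' @return A list with elements `s` (numeric vector), `rho` (integer) and
#'   `g` (numeric vector indexed by distance `1..rho`).
#' @export
distanceSpectrum <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) != ncol(dist)) stop("'dist' must be square")
  s <- rowSums(dist)
  rho <- as.integer(max(dist))
  ut <- dist[upper.tri(dist)]
  g <- if (rho >= 1L) tabulate(ut, nbins = rho) else numeric(0)
  list(s = s, rho = rho, g = g)
}

# Resolve the optional `dist` argument (matrix or NULL).
.dist_of <- function(g, dist) {
  if (is.null(dist)) distanceMatrix(g) else as.matrix(dist)
}

#' Graph generators
#'
#' Deterministic and seeded random generators used as fixtures and inputs:
#' the path `P_n`, star `K_{1,n-1}`, cycle `C_n`, complete graph `K_n`, a
#' uniform random labelled tree (Pruefer construction), and a connected
#' Erdos-Renyi graph (resampled until connected).
#'
#' @param n Number of vertices (`n >= 2`; `n >= 3` for cycles).
#' @param p Edge probability for [erdosRenyi()], in `(0, 1]`.
#' @param seed Integer seed; the global RNG state is restored on exit.
#' @param maxTries Resampling budget for connectivity.
#' @return A validated graph (see [buildGraph()]).
#' @name generators
NULL

#' @rdname generators
#' @export
pathGraph <- function(n) {
  stopifnot(n >= 2)
  buildGraph(n, cbind(seq_len(n - 1), seq_len(n - 1) + 1L))
}

#' @rdname generators
#' @export
starGraph <- function(n) {
  stopifnot(n >= 2)
  buildGraph(n, cbind(1L, 2:n))
}

#' @rdname generators
#' @export
cycleGraph <- function(n) {
  stopifnot(n >= 3)
  buildGraph(n, rbind(cbind(seq_len(n - 1), seq_len(n - 1) + 1L), c(n, 1L)))
}

#' @rdname generators
#' @export
completeGraph <- function(n) {
  stopifnot(n >= 2)
  buildGraph(n, t(utils::combn(n, 2)))
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# Decode a Pruefer sequence into tree edges (labels 1..n).
.prufer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (x in seq) degree[x] <- degree[x] + 1L
  edges <- matrix(0L, nrow = n - 1L, ncol = 2L)
  ptr <- 0L
  for (i in seq_along(seq)) {
    leaf <- which(degree == 1L)[1L]
    ptr <- ptr + 1L
    edges[ptr, ] <- c(leaf, seq[i])
    degree[leaf] <- 0L
    degree[seq[i]] <- degree[seq[i]] - 1L
  }
  edges[n - 1L, ] <- which(degree == 1L)
  edges
}

#' @rdname generators
#' @export
randomTree <- function(n, seed = NULL) {
  stopifnot(n >= 2)
  if (n == 2L) return(buildGraph(2L, cbind(1L, 2L)))
  .with_seed(seed, {
    prufer <- sample.int(n, n - 2L, replace = TRUE)
    buildGraph(n, .prufer_decode(prufer, n))
  })
}

#' @rdname generators
#' @export
erdosRenyi <- function(n, p, seed = NULL, maxTries = 200L) {
  stopifnot(n >= 2, p > 0, p <= 1)
  pairs <- t(utils::combn(n, 2))
  g <- .with_seed(seed, {
    found <- NULL
    for (k in seq_len(maxTries)) {
      keep <- stats::runif(nrow(pairs)) < p
      if (sum(keep) >= n - 1L) {
        cand <- buildGraph(n, pairs[keep, , drop = FALSE])
        if (igraph::is_connected(cand)) {
          found <- cand
          break
        }
      }
    }
    found
  })
  if (is.null(g)) {
    stop(sprintf("no connected graph found in %d tries (n=%d, p=%g)",
                 maxTries, n, p))
  }
  g
}

#' The six small example trees
#'
#' A named collection of six trees on 7 vertices, ordered from the path
#' (`"a"`) to the star (`"f"`) with branching -- the number of terminal
#' vertices -- increasing along the way. They exercise the contrast between
#' branching-sensitive descriptors (Wiener index decreases monotonically
#' across the collection) and symmetry-based ones (orbit entropy does not).
#'
#' @return Named list of six graphs keyed `"a".."f"`.
#' @examples
#' sapply(exampleTrees(), wiener)
#' @export
exampleTrees <- function() {
  e <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  list(
    a = buildGraph(7, e(1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6, 7)),
    b = buildGraph(7, e(1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 2, 7)),
    c = buildGraph(7, e(1, 2, 2, 3, 3, 4, 4, 5, 2, 6, 4, 7)),
    d = buildGraph(7, e(1, 2, 2, 3, 1, 4, 4, 5, 1, 6, 1, 7)),
    e = buildGraph(7, e(1, 2, 1, 3, 1, 4, 1, 5, 2, 6, 2, 7)),
    f = buildGraph(7, e(1, 2, 1, 3, 1, 4, 1, 5, 1, 6, 1, 7))
  )
}
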