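#' Adjacency- and degree-based descriptors
#'
#' Descriptors that need only the adjacency structure, not distances:
#'
#' * `totalAdjacency`: `A = 1/2 sum_ij a_ij`, i.e. the edge count `m`.
#' * `zagreb1`: first Zagreb group index `Z1 = sum_v deg(v)^2`.
#' * `zagreb2`: second Zagreb group index
#'   `Z2 = sum_{(u,v) in E} deg(u) deg(v)`.
#' * `randic`: connectivity index
#'   `R = sum_{(u,v) in E} (deg(u) deg(v))^(-1/2)`; equals `n/2` on any
#'   regular graph.
#' * `normalizedEdgeComplexity`: `E_N = 2m / n^2`, the adjacency-matrix
#'   density normalised by `n^2` (documented convention).
#'
#' @param g An undirected simple graph (connectivity is not required for
#'   these; `randic` rejects isolated vertices).
#' @return Numeric scalar.
#' @examples
#' zagreb1(starGraph(7))  # 42
#' randic(starGraph(7))   # 6/sqrt(6)
#' @name adjacency_descriptors
NULL

#' @rdname adjacency_descriptors
#' @export
totalAdjacency <- function(g) {
  .check_graph(g, connected = FALSE)
  as.numeric(igraph::ecount(g))
}

#' @rdname adjacency_descriptors
#' @export
zagreb1 <- function(g) {
  .check_graph(g, connected = FALSE)
  sum(igraph::degree(g)^2)
}

#' @rdname adjacency_descriptors
#' @export
zagreb2 <- function(g) {
  .check_graph(g, connected = FALSE)
  deg <- igraph::degree(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  sum(deg[el[, 1]] * deg[el[, 2]])
}

#' @rdname adjacency_descriptors
#' @export
randic <- function(g) {
  .check_graph(g, connected = FALSE)
  deg <- igraph::degree(g)
  if (any(deg == 0)) stop("randic is undefined for graphs with isolated vertices")
  el <- igraph::as_edgelist(g, names = FALSE)
  sum(1 / sqrt(deg[el[, 1]] * deg[el[, 2]]))
}

#' @rdname adjacency_descriptors
#' @export
normalizedEdgeComplexity <- function(g) {
  .check_graph(g, connected = FALSE)
  2 * igraph::ecount(g) / igraph::vcount(g)^2
}

#' Complexity index B
#'
#' `B = sum_v deg(v) / s_v`, each vertex's degree weighted by the inverse
#' of its distance degree. The degree-over-distance-degree form (without a
#' `1/n` normalisation) is the documented convention of this package.
#'
#' @inheritParams wiener
#' @return Numeric scalar.
#' @export
complexityIndexB <- function(g, dist = NULL) {
  .check_graph(g)
  s <- rowSums(.dist_of(g, dist))
  sum(igraph::degree(g) / s)
}
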