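#' Wiener index
#'
#' Half the sum of all pairwise shortest-path distances,
#' `W = 1/2 * sum_ij d_ij`. A classical branching-sensitive descriptor:
#' among trees on `n` vertices it is maximal for the path and minimal for
#' the star, and it decreases as branching (the number of terminal
#' vertices) increases.
#'
#' @param g A connected undirected simple graph.
#' @param dist Optional precomputed distance matrix ([distanceMatrix()]);
#'   computed internally when `NULL`.
#' @return Numeric scalar (integer-valued on unweighted graphs).
#' @examples
#' wiener(pathGraph(7))  # 56
#' @export
wiener <- function(g, dist = NULL) {
  .check_graph(g)
  sum(.dist_of(g, dist)) / 2
}

#' Harary index
#'
#' Reciprocal-distance sum `H = 1/2 * sum_{i != j} 1/d_ij^exponent`. The
#' literature contains both the `1/d` and `1/d^2` variants; the default is
#' `exponent = 1`.
#'
#' @inheritParams wiener
#' @param exponent Power applied to each distance before inverting.
#' @return Numeric scalar.
#' @export
harary <- function(g, dist = NULL, exponent = 1) {
  .check_graph(g)
  d <- .dist_of(g, dist)
  sum(1 / d[upper.tri(d)]^exponent)
}

#' Balaban J index
#'
#' `J = m/(gamma + 1) * sum_{(u,v) in E} (s_u * s_v)^(-1/2)` where `s_i`
#' is the distance degree (row sum of the distance matrix) and `gamma` the
#' cyclomatic number. A highly discriminating distance-based index.
#'
#' @inheritParams wiener
#' @return Numeric scalar.
#' @examples
#' balabanJ(pathGraph(7))  # heptane skeleton, ~2.4475
#' @export
balabanJ <- function(g, dist = NULL) {
  .check_graph(g)
  s <- rowSums(.dist_of(g, dist))
  el <- igraph::as_edgelist(g, names = FALSE)
  m <- igraph::ecount(g)
  gam <- m - igraph::vcount(g) + 1L
  m / (gam + 1) * sum(1 / sqrt(s[el[, 1]] * s[el[, 2]]))
}

#' Compactness
#'
#' Twice the mean pairwise distance, `C = 4W / (n(n-1))`. This normalisation
#' is a documented convention of this package (several variants exist in
#' the literature); it equals 2 for complete graphs and grows with graph
#' "spread".
#'
#' @inheritParams wiener
#' @return Numeric scalar.
#' @export
compactness <- function(g, dist = NULL) {
  .check_graph(g)
  n <- igraph::vcount(g)
  if (n < 2) stop("compactness requires at least two vertices")
  4 * wiener(g, dist) / (n * (n - 1))
}

#' Product of distance-matrix row sums
#'
#' `PRS = prod_i s_i`. The raw product overflows double precision around
#' `n ~ 30`, so the default returns `log2(PRS) = sum_i log2(s_i)`; set
#' `logScale = FALSE` for the raw product on small graphs.
#'
#' @inheritParams wiener
#' @param logScale Return `log2` of the product (default) instead of the
#'   raw product.
#' @return Numeric scalar.
#' @export
productOfRowSums <- function(g, dist = NULL, logScale = TRUE) {
  .check_graph(g)
  if (igraph::vcount(g) < 2) stop("productOfRowSums requires at least two vertices")
  s <- rowSums(.dist_of(g, dist))
  if (logScale) sum(log2(s)) else prod(s)
}

#' Hyper-distance-path index
#'
#' `D_P = sum_{i<j} (d_ij + d_ij^2)/2 = W + sum_{i<j} choose(d_ij, 2)`,
#' the hyper-Wiener-type extension of the Wiener index. Coincides with `W`
#' exactly on graphs of diameter 1.
#'
#' @inheritParams wiener
#' @return Numeric scalar.
#' @export
hyperDistancePath <- function(g, dist = NULL) {
  .check_graph(g)
  d <- .dist_of(g, dist)
  ut <- d[upper.tri(d)]
  sum(ut + ut^2) / 2
}

#' Skorobogatov-Dobrynin distance-degree statistics
#'
#' The family of vertex distance statistics and their graph-level
#' aggregates: eccentricities `e(v) = max_u d_vu`, radius, diameter, mean
#' eccentricity, distance degrees `s_v`, mean distance `2W/(n(n-1))`,
#' unipolarity `min_v s_v`, centralization `2W - n * min_v s_v`, variation
#' `max_v (s_v - min_u s_u)`, and the mean distance-degree deviation
#' `(1/n) sum_v |s_v - 2W/n|`. The member set and naming are frozen here;
#' the historical literature is ambiguous about the exact list.
#'
#' @inheritParams wiener
#' @return Named list with elements `eccentricity`, `radius`, `diameter`,
#'   `meanEccentricity`, `distanceDegree`, `meanDistance`, `unipolarity`,
#'   `centralization`, `variation`, `meanDistanceDeviation`.
#' @examples
#' dobrynin(starGraph(7))$centralization  # 30
#' @export
dobrynin <- function(g, dist = NULL) {
  .check_graph(g)
  d <- .dist_of(g, dist)
  n <- nrow(d)
  ecc <- apply(d, 1L, max)
  s <- rowSums(d)
  W <- sum(s) / 2
  list(
    eccentricity = ecc,
    radius = min(ecc),
    diameter = max(ecc),
    meanEccentricity = mean(ecc),
    distanceDegree = s,
    meanDistance = if (n > 1) 2 * W / (n * (n - 1)) else 0,
    unipolarity = min(s),
    centralization = 2 * W - n * min(s),
    variation = max(s - min(s)),
    meanDistanceDeviation = mean(abs(s - 2 * W / n))
  )
}
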