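#' Shannon entropy of a partition
#'
#' `-sum_k (n_k/N) log2(n_k/N)` over class sizes `n_k` with
#' `N = sum_k n_k`, using the convention `0 * log 0 = 0`. All entropies in
#' this package are in bits (base-2 logarithms).
#'
#' @param sizes Positive integer class sizes.
#' @param total Total element count; must equal `sum(sizes)` when given.
#' @return Entropy in bits, in `[0, log2(length(sizes) * max size)]`.
#' @examples
#' shannonEntropy(c(6, 1))  # star orbit partition, 0.5917 bits
#' @export
shannonEntropy <- function(sizes, total = sum(sizes)) {
  if (any(sizes <= 0) || any(sizes != round(sizes))) {
    stop("'sizes' must be positive integers")
  }
  if (sum(sizes) != total) stop("sum(sizes) must equal 'total'")
  p <- sizes / total
  -sum(p * log2(p))
}

#' Automorphism orbits of the vertex set
#'
#' Exact orbits of the graph's automorphism group: two vertices are in the
#' same orbit iff some adjacency-preserving permutation maps one onto the
#' other. Generators of the automorphism group are obtained from the BLISS
#' backend in igraph and closed into orbits by union-find (generators
#' suffice: the orbit of `v` under the group equals its orbit under any
#' generating set).
#'
#' @param g An undirected simple graph.
#' @return A list with `classes` (list of vertex-index vectors, one per
#'   orbit, ordered by smallest member) and `sizes` (class sizes, sorted
#'   decreasing).
#' @examples
#' vertexOrbits(pathGraph(7))$sizes  # 2 2 2 1
#' @export
vertexOrbits <- function(g) {
  .check_graph(g, connected = FALSE)
  n <- igraph::vcount(g)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  gens <- igraph::automorphism_group(g)
  for (p in gens) {
    pv <- as.integer(p)
    for (i in seq_len(n)) {
      a <- find(i)
      b <- find(pv[i])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  classes <- unname(split(seq_len(n), roots))
  classes <- classes[order(vapply(classes, min, 1L))]
  list(classes = classes,
       sizes = sort(lengths(classes), decreasing = TRUE))
}

#' Topological information content
#'
#' Shannon entropy of the automorphism-orbit partition of the vertex set:
#' `I_orb = -sum_k (|O_k|/n) log2(|O_k|/n)`. A symmetry measure -- zero for
#' vertex-transitive graphs, `log2 n` for graphs with trivial automorphism
#' group -- rather than a branching measure.
#'
#' @inheritParams wiener
#' @return List with `entropy` (bits) and `orbits` (orbit class sizes,
#'   sorted decreasing).
#' @examples
#' topologicalInfoContent(exampleTrees()$c)
#' @export
topologicalInfoContent <- function(g, dist = NULL) {
  .check_graph(g)
  orb <- vertexOrbits(g)
  list(entropy = shannonEntropy(orb$sizes), orbits = orb$sizes)
}

#' Bonchev-Trinajstic information indices on distances
#'
#' Information-theoretic summaries of the distance-frequency spectrum
#' `g_k` (number of unordered pairs at distance `k`):
#'
#' * `bonchev1` (equality form): `I_D = K log2 K - sum_k g_k log2 g_k`
#'   with `K = n(n-1)/2` unordered pairs (diagonal excluded). The total
#'   form over all pairs is used, not the mean form.
#' * `bonchev2` (magnitude form):
#'   `I_D^W = W log2 W - sum_k g_k k log2 k`.
#'
#' @inheritParams wiener
#' @return Numeric scalar (bits-weighted counts).
#' @name bonchev
NULL

#' @rdname bonchev
#' @export
bonchev1 <- function(g, dist = NULL) {
  .check_graph(g)
  if (igraph::vcount(g) < 2) stop("bonchev1 requires at least two vertices")
  sp <- distanceSpectrum(.dist_of(g, dist))
  K <- sum(sp$g)
  gk <- sp$g[sp$g > 0]
  K * log2(K) - sum(gk * log2(gk))
}

#' @rdname bonchev
#' @export
bonchev2 <- function(g, dist = NULL) {
  .check_graph(g)
  if (igraph::vcount(g) < 2) stop("bonchev2 requires at least two vertices")
  sp <- distanceSpectrum(.dist_of(g, dist))
  W <- sum(sp$s) / 2
  k <- seq_along(sp$g)
  W * log2(W) - sum(sp$g * k * log2(k))
}

#' Bertz complexity index
#'
#' Degree-based variant: `C = 2m log2(2m) - sum_v deg(v) log2(deg(v))`,
#' the information content of the degree sequence relative to the total
#' adjacency `2m`.
#'
#' @param g An undirected simple graph with at least one edge.
#' @return Numeric scalar.
#' @export
bertz <- function(g) {
  .check_graph(g, connected = FALSE)
  m <- igraph::ecount(g)
  if (m < 1) stop("bertz requires at least one edge")
  deg <- igraph::degree(g)
  deg <- deg[deg > 0]
  2 * m * log2(2 * m) - sum(deg * log2(deg))
}

#' Radial centric information index
#'
#' Shannon entropy of the eccentricity partition: vertices are equivalent
#' when they have equal eccentricity `e(v) = max_u d_vu`.
#'
#' @inheritParams wiener
#' @return List with `entropy` (bits) and `classes` (class sizes, sorted
#'   decreasing).
#' @export
radialCentric <- function(g, dist = NULL) {
  .check_graph(g)
  ecc <- apply(.dist_of(g, dist), 1L, max)
  sizes <- sort(as.integer(table(ecc)), decreasing = TRUE)
  list(entropy = shannonEntropy(sizes), classes = sizes)
}

#' Vertex-degree equality information index
#'
#' Shannon entropy of the degree partition: vertices are equivalent when
#' they have equal degree. Zero exactly for regular graphs.
#'
#' @param g An undirected simple graph.
#' @return List with `entropy` (bits) and `classes` (class sizes, sorted
#'   decreasing).
#' @export
vertexDegreeEquality <- function(g) {
  .check_graph(g, connected = FALSE)
  sizes <- sort(as.integer(table(igraph::degree(g))), decreasing = TRUE)
  list(entropy = shannonEntropy(sizes), classes = sizes)
}

# Local information on distance magnitudes:
# u_i = s_i log2 s_i - sum_j d_ij log2 d_ij.
.local_distance_information <- function(d) {
  vapply(seq_len(nrow(d)), function(i) {
    di <- d[i, ]
    di <- di[di > 0]
    s <- sum(di)
    s * log2(s) - sum(di * log2(di))
  }, numeric(1))
}

# Balaban-type edge sum m/(gamma+1) * sum (x_u x_v)^(-1/2) over a local
# vertex invariant; +Inf with a warning when any invariant vanishes.
.balaban_like <- function(g, x, who) {
  el <- igraph::as_edgelist(g, names = FALSE)
  m <- igraph::ecount(g)
  gam <- m - igraph::vcount(g) + 1L
  if (any(x < .Machine$double.eps^0.5)) {
    warning(sprintf("In %s: Graphs with |V| < 3 result in: Inf!", who))
    return(Inf)
  }
  m / (gam + 1) * sum(1 / sqrt(x[el[, 1]] * x[el[, 2]]))
}

#' Balaban-like information indices U and X
#'
#' Balaban-J-type edge sums over local information invariants instead of
#' distance degrees. For `balabanlike1` (index `U`) the local invariant is
#' the information on distance magnitudes
#' `u_i = s_i log2 s_i - sum_j d_ij log2 d_ij`, and
#' `U = m/(gamma+1) sum_{(i,j) in E} (u_i u_j)^(-1/2)`.
#'
#' When a local invariant vanishes -- as on the two-vertex graph, where
#' all distances are 1 and `u_i = 0` -- the index is infinite: the value
#' `Inf` is returned together with a warning, not an error.
#'
#' `balabanlike2` (index `X`) is built the same way from a second local
#' invariant whose original definition is not reproduced here; the shipped
#' default uses `x_i = u_i`, so that `balabanlike2` coincides with
#' `balabanlike1`. This is a documented reconstruction, not a validated
#' formula.
#'
#' @inheritParams wiener
#' @return Numeric scalar, possibly `Inf` (flagged by a warning).
#' @examples
#' suppressWarnings(balabanlike1(buildGraph(2, cbind(1, 2))))  # Inf
#' @name balaban_like
NULL

#' @rdname balaban_like
#' @export
balabanlike1 <- function(g, dist = NULL) {
  .check_graph(g)
  u <- .local_distance_information(.dist_of(g, dist))
  .balaban_like(g, u, "balabanlike1")
}

#' @rdname balaban_like
#' @export
balabanlike2 <- function(g, dist = NULL) {
  .check_graph(g)
  x <- .local_distance_information(.dist_of(g, dist))
  .balaban_like(g, x, "balabanlike2")
}

#' Graph vertex complexity index
#'
#' Mean per-vertex entropy of the distance distribution:
#' `v_i = -sum_{k=0}^{rho} (n_ik/n) log2(n_ik/n)` where `n_ik` is the
#' number of vertices at distance exactly `k` from `i` (`n_i0 = 1`), and
#' `I_V = (1/n) sum_i v_i`.
#'
#' @inheritParams wiener
#' @return Numeric scalar in `[0, log2 n]`.
#' @export
graphVertexComplexity <- function(g, dist = NULL) {
  .check_graph(g)
  d <- .dist_of(g, dist)
  n <- nrow(d)
  rho <- max(d)
  vi <- vapply(seq_len(n), function(i) {
    counts <- c(1, tabulate(d[i, ][d[i, ] > 0], nbins = rho))
    counts <- counts[counts > 0]
    p <- counts / n
    -sum(p * log2(p))
  }, numeric(1))
  mean(vi)
}
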