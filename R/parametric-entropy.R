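#' j-sphere cardinalities of a vertex
#'
#' `|S_j(v)|` counts the vertices at shortest-path distance exactly `j`
#' from `v`, for `j = 1..rho` where `rho` is the graph diameter. The
#' counts sum to `n - 1`; entries beyond the vertex's eccentricity are 0.
#'
#' @inheritParams wiener
#' @param v Vertex label (1..n).
#' @return Integer vector of length `rho`.
#' @examples
#' jSpheres(exampleTrees()$c, 1)  # 1 2 1 2
#' @export
jSpheres <- function(g, v, dist = NULL) {
  .check_graph(g)
  d <- .dist_of(g, dist)
  n <- nrow(d)
  if (!is.numeric(v) || length(v) != 1L || v < 1 || v > n || v != round(v)) {
    stop(sprintf("unknown vertex '%s'", format(v)))
  }
  rho <- max(d)
  tabulate(d[v, ][d[v, ] > 0], nbins = rho)
}

#' Coefficient schemes for information functionals
#'
#' Weighting parameters `c_1..c_rho`, one per sphere index up to the
#' diameter `rho`, all positive and non-increasing:
#'
#' * `constant`: `c_j = 1`
#' * `linear`: `c_j = rho - j + 1`
#' * `quadratic`: `c_j = (rho - j + 1)^2`
#' * `exponential` (alias `exp`): `c_j = rho * exp(1 - j)`
#'
#' @param name Scheme name (see above).
#' @param rho Graph diameter (`>= 1`).
#' @return Numeric vector of length `rho`.
#' @examples
#' infoCoefficients("exponential", 4)
#' @export
infoCoefficients <- function(name = c("constant", "linear", "quadratic",
                                      "exponential", "exp"),
                             rho) {
  name <- match.arg(name)
  if (!is.numeric(rho) || length(rho) != 1L || rho < 1 || rho != round(rho)) {
    stop("'rho' must be a positive integer")
  }
  j <- seq_len(rho)
  switch(name,
    constant = rep(1, rho),
    linear = rho - j + 1,
    quadratic = (rho - j + 1)^2,
    exponential = ,
    exp = rho * exp(1 - j)
  )
}

.check_coeffs <- function(coeffs, rho) {
  if (length(coeffs) != rho) {
    stop(sprintf("coefficient vector has length %d but the diameter is %d",
                 length(coeffs), rho))
  }
  if (any(coeffs <= 0)) stop("coefficients must be positive")
  invisible(coeffs)
}

#' Information functionals
#'
#' Positive vertex functionals `f(v)` built from the j-sphere cardinalities
#' `|S_j(v)|` and a coefficient vector `c_1..c_rho`:
#'
#' * `sphere`: `f(v) = sum_j c_j |S_j(v)|`
#' * `pathlength`: `f(v) = sum_j c_j j |S_j(v)|` (total length of the
#'   shortest paths leaving `v`, weighted per sphere)
#' * `vertcent`: `f(v) = sum_j c_j |S_j(v)| / j` (a closeness-style
#'   centrality contribution)
#' * `degree`: `f(v) = sum_j c_j sum_{u in S_j(v)} deg(u)` (degree-degree
#'   association)
#'
#' The `sphere` functional is the reference definition; the other three are
#' documented reconstructions of the same construction pattern and carry no
#' validated reference values.
#'
#' @inheritParams wiener
#' @param coeffs Positive coefficient vector of length equal to the graph
#'   diameter (see [infoCoefficients()]).
#' @param infofunct One of `"sphere"`, `"pathlength"`, `"vertcent"`,
#'   `"degree"`.
#' @return Numeric vector `f(v_1)..f(v_n)`, all strictly positive on
#'   connected graphs with at least one edge.
#' @export
informationFunctional <- function(g, coeffs,
                                  infofunct = c("sphere", "pathlength",
                                                "vertcent", "degree"),
                                  dist = NULL) {
  infofunct <- match.arg(infofunct)
  .check_graph(g)
  d <- .dist_of(g, dist)
  n <- nrow(d)
  rho <- max(d)
  .check_coeffs(coeffs, rho)
  deg <- igraph::degree(g)
  j <- seq_len(rho)
  w <- switch(infofunct,
    sphere = coeffs,
    pathlength = coeffs * j,
    vertcent = coeffs / j,
    degree = coeffs
  )
  vapply(seq_len(n), function(v) {
    if (infofunct == "degree") {
      sum(vapply(j, function(k) sum(deg[d[v, ] == k]), numeric(1)) * w)
    } else {
      sum(tabulate(d[v, ][d[v, ] > 0], nbins = rho) * w)
    }
  }, numeric(1))
}

#' Parametric graph entropy (information-functional entropy)
#'
#' Assigns each vertex the probability
#' `p_i = f(v_i) / sum_j f(v_j)` induced by an information functional `f`
#' (see [informationFunctional()]), and returns the entropy
#' `I_f = -sum_i p_i log2 p_i` together with its scaled distance from the
#' maximum entropy, `distance = lambda * (log2 n - I_f)`.
#'
#' The entropy is invariant under the scaling constant `lambda` (which only
#' affects `distance`) and under uniform rescaling of the coefficient
#' vector; it attains `log2 n` exactly when `f` is uniform over vertices,
#' e.g. on any vertex-transitive graph.
#'
#' @inheritParams wiener
#' @param infofunct Information functional name; see
#'   [informationFunctional()].
#' @param coeff Coefficient scheme name for [infoCoefficients()], ignored
#'   when `custCoeff` is given.
#' @param lambda Positive scaling constant for the distance from maximum
#'   entropy (default 1000).
#' @param custCoeff Optional custom positive coefficient vector of length
#'   equal to the graph diameter.
#' @return List with `entropy` (bits), `distance`, `pis` (vertex
#'   probabilities, named by vertex label) and `fvis` (functional values,
#'   named by vertex label).
#' @examples
#' infoTheoreticGCM(exampleTrees()$c, infofunct = "sphere",
#'                  coeff = "exp", lambda = 2500)$entropy
#' @export
infoTheoreticGCM <- function(g, dist = NULL,
                             infofunct = c("sphere", "pathlength",
                                           "vertcent", "degree"),
                             coeff = "exp", lambda = 1000,
                             custCoeff = NULL) {
  infofunct <- match.arg(infofunct)
  .check_graph(g)
  n <- igraph::vcount(g)
  if (n < 2) stop("infoTheoreticGCM requires at least two vertices")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop("'lambda' must be a positive number")
  }
  d <- .dist_of(g, dist)
  rho <- max(d)
  coeffs <- if (is.null(custCoeff)) {
    infoCoefficients(coeff, rho)
  } else {
    .check_coeffs(custCoeff, rho)
  }
  f <- informationFunctional(g, coeffs, infofunct = infofunct, dist = d)
  p <- f / sum(f)
  entropy <- -sum(p * log2(p))
  labels <- as.character(seq_len(n))
  names(p) <- labels
  names(f) <- labels
  list(entropy = entropy,
       distance = lambda * (log2(n) - entropy),
       pis = p,
       fvis = f)
}

#' Kullback-Leibler divergence
#'
#' `KL(p || q) = sum_i p_i log2(p_i / q_i)` in bits, for comparing the
#' vertex probability distributions of two networks (e.g. the `pis` of two
#' [infoTheoreticGCM()] results on graphs of equal order). Non-negative,
#' zero iff `p = q`; requires `q_i > 0` wherever `p_i > 0`.
#'
#' @param p,q Probability vectors of equal length, each summing to 1.
#' @return Divergence in bits.
#' @examples
#' klDivergence(c(0.5, 0.5), c(0.25, 0.75))
#' @export
klDivergence <- function(p, q) {
  if (length(p) != length(q)) stop("'p' and 'q' must have equal length")
  if (any(p < 0) || any(q < 0)) stop("probabilities must be non-negative")
  tol <- 1e-9
  if (abs(sum(p) - 1) > tol || abs(sum(q) - 1) > tol) {
    stop("'p' and 'q' must each sum to 1")
  }
  if (any(p > 0 & q == 0)) {
    stop("support violation: q is zero where p has mass")
  }
  keep <- p > 0
  sum(p[keep] * log2(p[keep] / q[keep]))
}
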