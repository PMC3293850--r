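# Independent oracles used by the property tests. These deliberately avoid
# the code paths (and the igraph algorithms) they are checking.

# Floyd-Warshall all-pairs shortest paths from the adjacency matrix.
fw_distances <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  d[A == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  d
}

# Exhaustive enumeration of all adjacency-preserving bijections by
# backtracking (degree-compatible images only; the pruning never discards a
# valid automorphism). Returns the orbit partition as a list of vertex sets.
brute_orbits <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  deg <- rowSums(A)
  same <- diag(n) > 0
  perm <- integer(n)
  used <- logical(n)
  rec <- function(i) {
    if (i > n) {
      for (v in seq_len(n)) {
        same[v, perm[v]] <<- TRUE
        same[perm[v], v] <<- TRUE
      }
      return(invisible(NULL))
    }
    for (img in which(!used & deg == deg[i])) {
      ok <- TRUE
      for (j in seq_len(i - 1L)) {
        if (A[i, j] != A[img, perm[j]]) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        perm[i] <<- img
        used[img] <<- TRUE
        rec(i + 1L)
        used[img] <<- FALSE
      }
    }
  }
  rec(1L)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (same[i, j]) {
        a <- find(i)
        b <- find(j)
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
  }
  unname(split(seq_len(n), vapply(seq_len(n), find, 1L)))
}

# All free (unlabelled) trees on exactly n vertices, enumerated by leaf
# augmentation with canonical-form deduplication. Counts for n = 2..8 are
# 1, 1, 2, 3, 6, 11, 23.
free_trees <- function(n) {
  canon_key <- function(g) {
    cp <- igraph::canonical_permutation(g)$labeling
    h <- igraph::permute(g, cp)
    el <- igraph::as_edgelist(h, names = FALSE)
    el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
    paste(t(el), collapse = ",")
  }
  trees <- list(buildGraph(2, cbind(1, 2)))
  k <- 2L
  while (k < n) {
    k <- k + 1L
    seen <- character(0)
    nxt <- list()
    for (tr in trees) {
      el <- igraph::as_edgelist(tr, names = FALSE)
      for (v in seq_len(k - 1L)) {
        cand <- buildGraph(k, rbind(el, c(v, k)))
        key <- canon_key(cand)
        if (!key %in% seen) {
          seen <- c(seen, key)
          nxt[[length(nxt) + 1L]] <- cand
        }
      }
    }
    trees <- nxt
  }
  trees
}

# Random connected graph helper for property tests.
rand_conn <- function(n, p = 0.4, seed = NULL) {
  erdosRenyi(n, p, seed = seed)
}

# Random relabelling of a graph (returns an isomorphic graph on labels 1..n).
shuffle_graph <- function(g, seed = NULL) {
  n <- igraph::vcount(g)
  perm <- netquant:::.with_seed(seed, sample.int(n))
  el <- igraph::as_edgelist(g, names = FALSE)
  buildGraph(n, cbind(perm[el[, 1]], perm[el[, 2]]))
}

# Sorted orbit-size vector from a partition list.
sizes_of <- function(classes) sort(lengths(classes), decreasing = TRUE)
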