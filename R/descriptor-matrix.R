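# Registry of scalar descriptors. Each entry is a function (g, dist) ->
# named numeric vector (usually length 1); list-returning descriptors are
# reduced to their entropy component here.
.descriptor_registry <- function() {
  list(
    wiener = function(g, d) c(wiener = wiener(g, d)),
    harary = function(g, d) c(harary = harary(g, d)),
    balabanJ = function(g, d) c(balabanJ = balabanJ(g, d)),
    compactness = function(g, d) c(compactness = compactness(g, d)),
    productOfRowSums = function(g, d)
      c(productOfRowSums = productOfRowSums(g, d)),
    hyperDistancePath = function(g, d)
      c(hyperDistancePath = hyperDistancePath(g, d)),
    dobrynin = function(g, d) {
      r <- dobrynin(g, d)
      c(dobrynin.radius = r$radius,
        dobrynin.diameter = r$diameter,
        dobrynin.meanEccentricity = r$meanEccentricity,
        dobrynin.meanDistance = r$meanDistance,
        dobrynin.unipolarity = r$unipolarity,
        dobrynin.centralization = r$centralization,
        dobrynin.variation = r$variation,
        dobrynin.meanDistanceDeviation = r$meanDistanceDeviation)
    },
    totalAdjacency = function(g, d) c(totalAdjacency = totalAdjacency(g)),
    zagreb1 = function(g, d) c(zagreb1 = zagreb1(g)),
    zagreb2 = function(g, d) c(zagreb2 = zagreb2(g)),
    randic = function(g, d) c(randic = randic(g)),
    complexityIndexB = function(g, d)
      c(complexityIndexB = complexityIndexB(g, d)),
    normalizedEdgeComplexity = function(g, d)
      c(normalizedEdgeComplexity = normalizedEdgeComplexity(g)),
    topologicalInfoContent = function(g, d)
      c(topologicalInfoContent = topologicalInfoContent(g, d)$entropy),
    bonchev1 = function(g, d) c(bonchev1 = bonchev1(g, d)),
    bonchev2 = function(g, d) c(bonchev2 = bonchev2(g, d)),
    bertz = function(g, d) c(bertz = bertz(g)),
    radialCentric = function(g, d)
      c(radialCentric = radialCentric(g, d)$entropy),
    vertexDegreeEquality = function(g, d)
      c(vertexDegreeEquality = vertexDegreeEquality(g)$entropy),
    balabanlike1 = function(g, d) c(balabanlike1 = balabanlike1(g, d)),
    balabanlike2 = function(g, d) c(balabanlike2 = balabanlike2(g, d)),
    graphVertexComplexity = function(g, d)
      c(graphVertexComplexity = graphVertexComplexity(g, d))
  )
}

#' Available descriptor names
#'
#' Names accepted by [computeDescriptorMatrix()]; `"dehmer"` additionally
#' selects the parametric entropy with the matrix-level `infofunct`,
#' `coeff` and `lambda` settings.
#'
#' @return Character vector.
#' @export
listDescriptors <- function() {
  c(names(.descriptor_registry()), "dehmer")
}

#' Compute a descriptor matrix over a graph collection
#'
#' Evaluates a set of descriptors for every graph in a named collection and
#' returns the graphs x descriptors feature matrix. The distance matrix of
#' each graph is computed once and shared across all descriptors. Warnings
#' raised by individual descriptors (e.g. the `Inf` of the Balaban-like
#' indices on two-vertex graphs) are collected per cell; a graph that fails
#' validation yields a row of `NA` flagged `"undefined"` rather than
#' aborting the run. Output is deterministic: fixed column order, one row
#' per input graph.
#'
#' @param graphs Named list of graphs (see [buildGraph()],
#'   [readGraphCollection()]); names are the row identifiers.
#' @param descriptors Character vector of descriptor names
#'   ([listDescriptors()]) or `"all"`. Unknown names are rejected before
#'   any computation.
#' @param infofunct,coeff,lambda Settings for the `"dehmer"` column; see
#'   [infoTheoreticGCM()].
#' @param custCoeff Optional custom coefficient vector for `"dehmer"`.
#' @return A data.frame with one row per graph (rownames = identifiers)
#'   and one numeric column per descriptor. Attributes: `flags` (character
#'   matrix, `"finite"`, `"infinite"` or `"undefined"` per cell),
#'   `warnings` (named list of per-graph warning messages) and
#'   `provenance` (list of the parametric-entropy settings).
#' @examples
#' m <- computeDescriptorMatrix(exampleTrees(), c("wiener", "balabanJ"))
#' m$wiener
#' @export
computeDescriptorMatrix <- function(graphs, descriptors = "all",
                                    infofunct = "sphere", coeff = "exp",
                                    lambda = 1000, custCoeff = NULL) {
  if (!is.list(graphs) || length(graphs) == 0) {
    stop("'graphs' must be a non-empty named list of graphs")
  }
  ids <- names(graphs)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids)) {
    stop("'graphs' must have unique non-empty names")
  }
  registry <- .descriptor_registry()
  if (identical(descriptors, "all")) descriptors <- listDescriptors()
  unknown <- setdiff(descriptors, listDescriptors())
  if (length(unknown)) {
    stop(sprintf("unknown descriptor(s): %s", paste(unknown, collapse = ", ")))
  }
  funs <- registry[intersect(descriptors, names(registry))]
  if ("dehmer" %in% descriptors) {
    funs$dehmer <- function(g, d) {
      c(dehmer = infoTheoreticGCM(g, dist = d, infofunct = infofunct,
                                  coeff = coeff, lambda = lambda,
                                  custCoeff = custCoeff)$entropy)
    }
  }

  warn_log <- stats::setNames(vector("list", length(graphs)), ids)
  rows <- lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    local_warnings <- character(0)
    row <- withCallingHandlers(
      tryCatch({
        .check_graph(g)
        d <- distanceMatrix(g)
        unlist(unname(lapply(funs, function(f) f(g, d))))
      }, error = function(e) {
        local_warnings <<- c(local_warnings, conditionMessage(e))
        NULL
      }),
      warning = function(w) {
        local_warnings <<- c(local_warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    warn_log[[i]] <<- local_warnings
    row
  })

  # Column layout from the first successful row; failed graphs get NA rows.
  template <- rows[[which(!vapply(rows, is.null, TRUE))[1L]]]
  if (is.null(template)) stop("no graph in the collection could be processed")
  cols <- names(template)
  mat <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(r)) stats::setNames(rep(NA_real_, length(cols)), cols) else r[cols]
  }))
  rownames(mat) <- ids
  flags <- matrix("finite", nrow = nrow(mat), ncol = ncol(mat),
                  dimnames = dimnames(mat))
  flags[is.infinite(mat)] <- "infinite"
  flags[is.na(mat)] <- "undefined"
  out <- as.data.frame(mat)
  attr(out, "flags") <- flags
  attr(out, "warnings") <- warn_log[vapply(warn_log, length, 1L) > 0]
  attr(out, "provenance") <- list(infofunct = infofunct, coeff = coeff,
                                  lambda = lambda, custCoeff = custCoeff)
  out
}

#' Write a descriptor matrix as TSV
#'
#' UTF-8 tab-separated output with the graph identifier in the first
#' column (`id`), values printed with 6 decimal places, `.` as decimal
#' separator, infinite cells as `Inf` and undefined cells as `NA`.
#' Identical inputs produce byte-identical files.
#'
#' @param mat Result of [computeDescriptorMatrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeDescriptorMatrix <- function(mat, path) {
  fmt <- function(x) {
    ifelse(is.na(x), "NA",
           ifelse(is.infinite(x), ifelse(x > 0, "Inf", "-Inf"),
                  sprintf("%.6f", x)))
  }
  cells <- vapply(mat, fmt, character(nrow(mat)))
  if (nrow(mat) == 1L) cells <- matrix(cells, nrow = 1L)
  out <- cbind(id = rownames(mat), cells)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(colnames(out), collapse = "\t"), con)
  writeLines(apply(out, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Generate a synthetic population of trees with tunable branching
#'
#' Random trees whose expected number of terminal vertices grows with
#' `branchingBias`. Each tree is grown vertex by vertex; the new vertex
#' attaches to the previously added vertex with probability
#' `1 - branchingBias` (path-like growth) and to the root hub (vertex 1)
#' otherwise. `branchingBias = 0` yields exactly the path;
#' `branchingBias = 1` yields exactly the star, with the expected leaf
#' count interpolating in between. Because the Wiener index decreases with
#' branching, populations generated at different biases separate on
#' distance-based descriptors -- a synthetic stand-in for comparing network
#' populations of different structural classes.
#'
#' @param nGraphs Number of trees (`>= 1`).
#' @param nVertices Vertices per tree (`>= 3`).
#' @param branchingBias Probability in `[0, 1]` of hub-forming attachment.
#' @param seed Integer seed; the run is reproducible.
#' @return Named list of graphs (`"g001"`, `"g002"`, ...).
#' @examples
#' pop <- generatePopulation(5, 10, branchingBias = 1, seed = 1)
#' sapply(pop, function(g) sum(igraph::degree(g) == 1))  # near n - 1
#' @export
generatePopulation <- function(nGraphs, nVertices, branchingBias, seed = NULL) {
  if (nGraphs < 1) stop("'nGraphs' must be >= 1")
  if (nVertices < 3) stop("'nVertices' must be >= 3")
  if (branchingBias < 0 || branchingBias > 1) {
    stop("'branchingBias' must lie in [0, 1]")
  }
  .with_seed(seed, {
    graphs <- lapply(seq_len(nGraphs), function(i) {
      edges <- matrix(0L, nrow = nVertices - 1L, ncol = 2L)
      for (v in 2:nVertices) {
        hub <- stats::runif(1) < branchingBias
        target <- if (hub) 1L else v - 1L
        edges[v - 1L, ] <- c(target, v)
      }
      buildGraph(nVertices, edges)
    })
    names(graphs) <- sprintf("g%03d", seq_len(nGraphs))
    graphs
  })
}
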