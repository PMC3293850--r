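---
title: "Topological network descriptors: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological network descriptors: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netquant)
```

## What the package computes

A topological network descriptor maps a graph to a number that depends only
on its structure: isomorphic graphs receive identical values. Such
descriptors turn a collection of biological networks — protein interaction
maps, inferred gene-regulatory networks, pathway subgraphs — into feature
vectors that can be compared, clustered or classified. netquant implements
four families on undirected simple connected graphs:

1. **Distance-based indices.** From the matrix of BFS shortest-path
   distances `d_ij`: the Wiener index `W = 1/2 Σ d_ij`, Harary index
   (reciprocal distances), Balaban `J`, compactness, product of
   distance-matrix row sums, the hyper-distance-path index, and the
   Skorobogatov–Dobrynin family of distance-degree statistics
   (eccentricities, unipolarity, centralization, variation, mean
   deviation).
2. **Other-invariant indices.** From degrees and adjacency alone: total
   adjacency, the two Zagreb group indices, the Randić connectivity index,
   complexity index `B`, and the normalized edge complexity.
3. **Partition-based entropies.** Shannon entropies (base 2 throughout,
   with `0·log 0 := 0`) over vertex partitions induced by an equivalence
   criterion: automorphism orbits (topological information content),
   eccentricity classes (radial centric index), degree classes, the
   distance-frequency spectrum (the two Bonchev–Trinajstić indices), the
   degree-sequence information of Bertz, the Balaban-like information
   indices `U` and `X`, and the mean per-vertex distance-distribution
   entropy (graph vertex complexity).
4. **Parametric entropies.** An information functional `f(v) > 0` built
   from the `j`-sphere cardinalities `|S_j(v)|` (vertices at distance
   exactly `j` from `v`) induces vertex probabilities
   `p_i = f(v_i)/Σ_j f(v_j)`; the descriptor is `I_f = −Σ p_i log2 p_i`,
   reported together with its scaled gap from the maximum,
   `distance = λ (log2 n − I_f)`.

Descriptors excluded by design: anything requiring subgraph-isomorphism
counting or the Hosoya index (NP-complete), weighted or directed variants,
and network *inference* — the package consumes networks, it does not build
them from expression data.

## The example trees and what they demonstrate

`exampleTrees()` returns six trees on 7 vertices ordered from the path
(`a`) to the star (`f`). Branching — the number of terminal vertices —
increases along the series, and the families react differently:

```{r}
tr <- exampleTrees()
round(rbind(
  wiener  = sapply(tr, wiener),
  I_orb   = sapply(tr, function(g) topologicalInfoContent(g)$entropy),
  I_sphere = sapply(tr, function(g) infoTheoreticGCM(g)$entropy)
), 4)
```

The Wiener index decreases strictly with branching; the orbit entropy does
not order the series at all because it measures symmetry, not branching
(the path and the three-armed tree `d` have the same orbit-size profile
`2,2,2,1`). This is the central caveat the package's documentation repeats:
a descriptor answers only the structural question it encodes.

The six trees are a reconstruction: they were chosen so that each matches
several independently printed invariants simultaneously (the Wiener and
orbit-entropy profiles above, the orbit sizes `4 2 1` of tree `c`, and the
per-vertex functional values of tree `c` under the exponential weighting).
Trees `b` and `d` are pinned by fewer invariants than the others; the test
suite marks the corresponding expectations as reconstruction-dependent.

## Conventions and tunable parameters

**Logarithms** are base 2 everywhere; entropies are in bits.

**Distances.** Every distance-based descriptor accepts `dist`, an optional
precomputed matrix from `distanceMatrix()`. Passing it is purely a
performance contract: results are identical with and without it (a
property test enforces this), but on large networks one BFS sweep shared
by ~25 descriptors matters. `computeDescriptorMatrix()` does this caching
automatically.

**Disconnected graphs are rejected**, not assigned infinite distances:
every descriptor here assumes finite distances, and no convention for the
disconnected case is established for this catalogue. Likewise, weighted or
directed input files raise errors instead of being silently coerced.

**Special values.** The Balaban-like indices are genuinely infinite on the
two-vertex graph (the local information invariant
`u_i = s_i log2 s_i − Σ_j d_ij log2 d_ij` vanishes when all distances are
1). The package returns `Inf` with a warning rather than raising an error,
and the descriptor matrix carries a per-cell flag
(`finite` / `infinite` / `undefined`) so that downstream summaries can
exclude flagged cells explicitly. `NA` rows mark graphs that failed
validation inside a batch run; they never abort the batch.

**Parametric-entropy parameters.** Diameter-length weight vectors
`c_1..c_rho` come from `infoCoefficients()`: `constant` (`c_j = 1`),
`linear` (`c_j = rho − j + 1`), `quadratic` (`(rho − j + 1)^2`) and
`exponential` (`c_j = rho·e^(1−j)`). The exponential rule is the reference
scheme: it reproduces the per-vertex functional values, probabilities and
entropies printed for the example trees to six decimals. The default
scaling constant is `λ = 1000`; `λ` affects only the distance-from-maximum
term, never the entropy, and the entropy is also invariant under uniform
rescaling of the coefficients — both invariances are asserted to machine
precision in the tests. Custom coefficient vectors must be positive and of
length `rho`.

**Reconstructed definitions.** Four formulas in the catalogue are
documented conventions of this package rather than validated reference
formulas, because the quantity's name has several variants in the
literature and no printed value pins one down: Harary uses `1/d` (an
`exponent` argument switches to `1/d^2`); compactness is `4W/(n(n−1))`;
complexity index `B` is `Σ_v deg(v)/s_v` unnormalized; Bertz uses the
degree-based form. The same applies to the `pathlength`, `vertcent` and
`degree` information functionals, which follow the same
sphere-sum pattern as the validated `sphere` functional, and to the second
Balaban-like invariant: `balabanlike2` ships with `x_i = u_i` and therefore
coincides with `balabanlike1`; its reference values on the example trees
have different magnitudes but the same strictly increasing branching
order, which is the behaviour the tests assert. None of these
reconstructed definitions backs an acceptance value.

**Orbit computation.** Exact automorphism orbits come from group
generators (BLISS, via igraph) closed under union-find; generators suffice
because the orbit of a vertex under a group equals its orbit under any
generating set. The test suite checks this against an independent
exhaustive enumeration of all adjacency-preserving bijections for every
free tree on up to 8 vertices and for random graphs. `productOfRowSums`
defaults to `log2` scale because the raw product overflows doubles near
`n ≈ 30`.

## The synthetic population generator

`generatePopulation()` grows random trees vertex-by-vertex: each new
vertex attaches to the previously added vertex with probability
`1 − branchingBias` and to the root hub otherwise, so bias 0 gives exactly
the path, bias 1 exactly the star, and intermediate biases interpolate the
expected leaf count. It emulates one thing only: *populations of networks
that differ in branching*, the structural axis along which the
distance-based descriptors separate. It does not emulate degree
distributions, modularity, cyclic structure or noise of real molecular
networks — passing the population-separation test (mean Wiener difference,
permutation p < 0.05 at 100 trees of 20 vertices per class) therefore shows
that the descriptor pipeline detects a known structural contrast, not that
it classifies real biological network collections.

## Numerical choices and problem sizes

Test problem sizes were chosen so the whole suite stays interactive: the
distance oracle runs 200 random graphs up to `n = 25` against
Floyd–Warshall; orbit checks cover all 43 free trees with 4–8 vertices plus
100 random graphs; extremality of the path/star Wiener index is verified
exhaustively over the same free-tree catalogue. Printed reference values
are asserted at the precision at which they are printed (4, 6 or 7
decimals); exact integers (Wiener on unweighted graphs) are compared
exactly. Ties in entropy bounds use a `1e-12` slack for floating-point
accumulation.

## Known limitations

* Orbit computation is exact but relies on practical automorphism-group
  algorithms; pathological highly regular graphs far beyond biological
  network sizes may be slow.
* `balabanlike2` awaits a validated second invariant (see above).
* The descriptor matrix averages nothing by design; consumers must decide
  how to treat `Inf`/`NA` flags.
* Only unweighted, undirected, connected graphs are supported, matching
  the domain on which the catalogue is defined.
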