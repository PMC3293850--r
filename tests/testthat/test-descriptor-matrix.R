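test_that("descriptor matrix covers the collection with shared distances", {
  tr <- exampleTrees()
  m <- computeDescriptorMatrix(tr, c("wiener", "topologicalInfoContent", "dehmer"),
                               infofunct = "sphere", coeff = "exp")
  expect_equal(rownames(m), letters[1:6])
  expect_equal(colnames(m), c("wiener", "topologicalInfoContent", "dehmer"))
  expect_equal(m$wiener, c(56, 52, 48, 44, 42, 36))
  expect_equal(m$dehmer, sapply(tr, function(g) infoTheoreticGCM(g)$entropy),
               ignore_attr = TRUE)
  expect_true(all(attr(m, "flags") == "finite"))
  expect_equal(attr(m, "provenance")$lambda, 1000)
})

test_that("unknown descriptors are rejected before computation", {
  expect_error(computeDescriptorMatrix(exampleTrees(), c("wiener", "nope")),
               "unknown descriptor")
  expect_error(computeDescriptorMatrix(list(), "wiener"), "non-empty")
  expect_error(computeDescriptorMatrix(unname(exampleTrees()), "wiener"),
               "names")
})

test_that("infinite cells are flagged and their warnings recorded", {
  graphs <- list(tiny = buildGraph(2, cbind(1, 2)), p4 = pathGraph(4))
  m <- computeDescriptorMatrix(graphs, c("wiener", "balabanlike1"))
  expect_identical(m["tiny", "balabanlike1"], Inf)
  expect_equal(attr(m, "flags")["tiny", "balabanlike1"], "infinite")
  expect_equal(attr(m, "flags")["p4", "balabanlike1"], "finite")
  expect_match(attr(m, "warnings")$tiny, "Inf", all = FALSE)
})

test_that("invalid graphs yield flagged NA rows, not a failed run", {
  graphs <- list(ok = pathGraph(5),
                 broken = buildGraph(4, rbind(c(1, 2), c(3, 4))))
  m <- computeDescriptorMatrix(graphs, c("wiener", "harary"))
  expect_equal(m["ok", "wiener"], 20)
  expect_true(all(is.na(m["broken", ])))
  expect_true(all(attr(m, "flags")["broken", ] == "undefined"))
})

test_that("TSV output is deterministic and encodes special values", {
  graphs <- c(exampleTrees(), list(tiny = buildGraph(2, cbind(1, 2))))
  m <- computeDescriptorMatrix(graphs, c("wiener", "balabanJ", "balabanlike1"))
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  writeDescriptorMatrix(m, f1)
  writeDescriptorMatrix(computeDescriptorMatrix(
    graphs, c("wiener", "balabanJ", "balabanlike1")), f2)
  expect_identical(readLines(f1), readLines(f2))
  lines <- readLines(f1)
  expect_equal(lines[1], "id\twiener\tbalabanJ\tbalabanlike1")
  expect_match(lines[grep("^tiny", lines)], "\tInf$")
  expect_match(lines[2], "^a\t56\\.000000\t")
})

test_that("cached and per-call distance matrices give identical results", {
  tr <- exampleTrees()
  m <- computeDescriptorMatrix(tr, "all")
  direct <- sapply(tr, function(g) balabanJ(g))  # recomputes distances itself
  expect_equal(m$balabanJ, unname(direct))
})

test_that("population generator spans path-like to star-like trees", {
  leaves <- function(g) sum(igraph::degree(g) == 1)
  paths <- generatePopulation(20, 12, branchingBias = 0, seed = 5)
  stars <- generatePopulation(20, 12, branchingBias = 1, seed = 5)
  expect_true(all(sapply(paths, leaves) == 2))
  expect_true(all(sapply(stars, leaves) == 11))
  mid <- generatePopulation(40, 12, branchingBias = 0.5, seed = 5)
  ml <- mean(sapply(mid, leaves))
  expect_gt(ml, 2)
  expect_lt(ml, 11)
  # reproducibility
  again <- generatePopulation(20, 12, branchingBias = 1, seed = 5)
  expect_identical(lapply(again, igraph::as_edgelist),
                   lapply(stars, igraph::as_edgelist))
})

test_that("low- and high-branching populations separate on the Wiener index", {
  popA <- generatePopulation(100, 20, branchingBias = 0.2, seed = 101)
  popB <- generatePopulation(100, 20, branchingBias = 0.8, seed = 202)
  wA <- sapply(popA, wiener)
  wB <- sapply(popB, wiener)
  expect_gt(mean(wA), mean(wB))
  # permutation test on the mean difference
  obs <- mean(wA) - mean(wB)
  pooled <- c(wA, wB)
  set.seed(303)
  perm <- replicate(999, {
    idx <- sample(length(pooled), length(wA))
    mean(pooled[idx]) - mean(pooled[-idx])
  })
  p <- (1 + sum(abs(perm) >= abs(obs))) / 1000
  expect_lt(p, 0.05)
})

test_that("the command-line interface computes fixture descriptor tables", {
  cli <- system.file("cli", "netquant.R", package = "netquant")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  out <- file.path(dir, "m.tsv")
  res1 <- system2("Rscript", c(cli, "fixtures", "--out", file.path(dir, "g"),
                               "--format", "graphml"))
  expect_equal(res1, 0)
  expect_length(list.files(file.path(dir, "g"), pattern = "graphml$"), 6)
  res2 <- system2("Rscript", c(cli, "compute", "--in", file.path(dir, "g"),
                               "--format", "graphml",
                               "--descriptors", "wiener,balabanJ,dehmer",
                               "--coeff", "exp", "--lambda", "2500",
                               "--out", out))
  expect_equal(res2, 0)
  tab <- read.delim(out)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$wiener, c(56, 52, 48, 44, 42, 36))
  expect_equal(tab$dehmer[tab$id == "c"], 2.743221, tolerance = 1e-6)
})
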