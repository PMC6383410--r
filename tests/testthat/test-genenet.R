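test_that("gene matrix counts joint publications with totals on the diagonal", {
  cp <- makeCorpus(genes = list(c("A", "B"), "A"))
  m <- counts(geneMatrix(cp))
  expect_equal(m["A", "B"], 1L)
  expect_equal(m["A", "A"], 2L)  # per-gene publication count
  expect_equal(m["B", "B"], 1L)
  expect_equal(diagonalSemantics(geneMatrix(cp)),
               "entity_publication_total")

  sim <- generateCorpus(syntheticSpec(nPubs = 100, nGenes = 30, seed = 17))
  got <- counts(geneMatrix(sim$corpus))
  sets <- lapply(records(sim$corpus)$genes, unique)
  sets <- sets[lengths(sets) > 0]
  oracle <- bfCooccurrence(sets, diagonalSelfOnly = FALSE)
  expect_equal(got, oracle)
})

test_that("thresholding is strict and monotone in theta", {
  m <- matrix(c(20L, 10L, 10L, 15L), 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(nrow(graphEdges(thresholdGraph(asCoocc(m), 10))), 0L)
  m["A", "B"] <- m["B", "A"] <- 11L
  tg <- thresholdGraph(asCoocc(m), 10)
  expect_equal(graphEdges(tg), cbind("A", "B"), ignore_attr = TRUE)
  expect_equal(tg@weights, 11)
  expect_error(thresholdGraph(asCoocc(m), -1), "theta")

  set.seed(3)
  n <- 20
  mm <- matrix(0L, n, n, dimnames = list(sprintf("g%02d", 1:n),
                                         sprintf("g%02d", 1:n)))
  mm[upper.tri(mm)] <- rpois(n * (n - 1) / 2, 6)
  mm <- mm + t(mm)
  prev <- NULL
  for (th in c(0, 2, 4, 6, 8, 12)) {
    tg <- thresholdGraph(asCoocc(mm), th)
    # brute-force filter oracle
    idx <- which(upper.tri(mm) & mm > th, arr.ind = TRUE)
    expect_equal(nrow(graphEdges(tg)), nrow(idx))
    key <- paste(graphEdges(tg)[, 1], graphEdges(tg)[, 2])
    if (!is.null(prev)) expect_true(all(key %in% prev))  # monotone nesting
    prev <- key
  }
  # theta = 0 keeps every realized co-occurrence
  expect_equal(nrow(graphEdges(thresholdGraph(asCoocc(mm), 0))),
               sum(mm[upper.tri(mm)] > 0))
})

test_that("a planted pair count of 52 survives to the thresholded edge", {
  base <- generateCorpus(syntheticSpec(nPubs = 500, seed = 19))$corpus
  cp <- plantGenePair(base, "KLK3", "NPEPPS", 52L, seed = 6)
  m <- counts(geneMatrix(cp))
  expect_equal(m["KLK3", "NPEPPS"], 52L)
  tg <- thresholdGraph(geneMatrix(cp), 10)
  e <- graphEdges(tg)
  expect_true(any(e[, 1] == "KLK3" & e[, 2] == "NPEPPS"))
})

test_that("exceedance probability is the realized-pair fraction", {
  m <- matrix(0L, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  # four co-occurring pairs, one above the threshold
  m["A", "B"] <- m["B", "A"] <- 12L
  m["A", "C"] <- m["C", "A"] <- 3L
  m["B", "C"] <- m["C", "B"] <- 10L
  m["C", "D"] <- m["D", "C"] <- 1L
  expect_equal(pairExceedanceProbability(asCoocc(m), 10), 0.25)
  expect_equal(pairExceedanceProbability(asCoocc(m), 100), 0)
  expect_equal(pairExceedanceProbability(asCoocc(m), 0), 1)
  z <- matrix(0L, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(pairExceedanceProbability(asCoocc(z), 10), "undefined")
})

test_that("communities are the connected components, largest first", {
  empty <- thresholdGraph(asCoocc(matrix(0L, 2, 2,
    dimnames = list(c("A", "B"), c("A", "B")))), 0)
  expect_equal(graphCommunities(empty), list())

  # two disjoint triangles plus an isolated vertex
  labs <- c("A", "B", "C", "D", "E", "F", "Z")
  m <- matrix(0L, 7, 7, dimnames = list(labs, labs))
  for (p in list(c("A","B"), c("B","C"), c("A","C"),
                 c("D","E"), c("E","F"), c("D","F")))
    m[p[1], p[2]] <- m[p[2], p[1]] <- 5L
  tg <- thresholdGraph(asCoocc(m), 0)
  comm <- graphCommunities(tg)
  expect_equal(comm, list(c("A", "B", "C"), c("D", "E", "F")))
  expect_equal(comm, bfComponents(graphEdges(tg)))
  # partition of the non-isolated labels
  expect_equal(sort(unlist(comm)), sort(setdiff(labs, "Z")))
})

test_that("a bridge gene joins two blocks into one component", {
  # two 3-cliques joined only through the hub gene "KLK3"
  labs <- c("KLK3", "a1", "a2", "a3", "b1", "b2", "b3")
  m <- matrix(0L, 7, 7, dimnames = list(labs, labs))
  link <- function(i, j) m[i, j] <<- m[j, i] <<- 20L
  for (p in utils::combn(c("a1", "a2", "a3"), 2, simplify = FALSE))
    link(p[1], p[2])
  for (p in utils::combn(c("b1", "b2", "b3"), 2, simplify = FALSE))
    link(p[1], p[2])
  link("KLK3", "a1"); link("KLK3", "b1")
  full <- graphCommunities(thresholdGraph(asCoocc(m), 10))
  expect_equal(length(full), 1L)
  # removing the bridge splits the graph into the two planted blocks
  m2 <- m[-1, -1]
  cut <- graphCommunities(thresholdGraph(asCoocc(m2), 10))
  expect_equal(cut, list(c("a1", "a2", "a3"), c("b1", "b2", "b3")))
})

test_that("graph exports round-trip the edge set", {
  labs <- c("A", "B", "C", "D")
  m <- matrix(0L, 4, 4, dimnames = list(labs, labs))
  m["A", "B"] <- m["B", "A"] <- 12L
  m["B", "C"] <- m["C", "B"] <- 15L
  m["A", "C"] <- m["C", "A"] <- 11L
  tg <- thresholdGraph(asCoocc(m), 10)

  f1 <- withr::local_tempfile(fileext = ".tsv")
  exportGraph(tg, f1, format = "edgelist")
  back <- importGraph(f1, format = "edgelist", theta = 10)
  expect_equal(graphEdges(back), graphEdges(tg))
  expect_equal(back@weights, tg@weights)

  f2 <- withr::local_tempfile(fileext = ".graphml")
  exportGraph(tg, f2, format = "graphml")
  back2 <- importGraph(f2, format = "graphml")
  expect_equal(graphEdges(back2), graphEdges(tg))
  expect_equal(sort(graphLabels(back2)), sort(graphLabels(tg)))
  expect_equal(theta(back2), 10)

  # empty graph: header-only edge list
  e <- thresholdGraph(asCoocc(m), 100)
  f3 <- withr::local_tempfile(fileext = ".tsv")
  exportGraph(e, f3, format = "edgelist")
  expect_equal(length(readLines(f3)), 1L)
  expect_equal(nrow(graphEdges(importGraph(f3, format = "edgelist"))), 0L)
})
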