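gcmFromMatrix <- function(m) new("GeneCityMatrix", counts = m)

test_that("gene-by-city counts credit every city of a publication", {
  cp <- makeCorpus(
    genes = list("A", "A", c("A", "B")),
    countries = list("Finland", "Finland", "Finland"),
    cities = list("Helsinki", c("Helsinki", "Tampere"), "Tampere"))
  m <- counts(geneCityMatrix(cp, c("A", "B"), "Finland"))
  expect_equal(m["A", "Helsinki"], 2L)
  expect_equal(m["A", "Tampere"], 2L)  # multi-city paper counts per city
  expect_equal(m["B", "Tampere"], 1L)
  expect_equal(m["B", "Helsinki"], 0L)
})

test_that("gene-by-city counts match a brute-force triple loop", {
  sim <- generateCorpus(syntheticSpec(nPubs = 150, nGenes = 40, seed = 29))
  cp <- annotateGeo(sim$corpus, focalCountry = "Finland")
  top <- topGenes(genePublicationCounts(cp), 10)
  got <- counts(geneCityMatrix(cp, top, "Finland"))
  rec <- records(cp)
  for (g in rownames(got)) for (ct in colnames(got)) {
    oracle <- 0L
    for (r in seq_len(nrow(rec)))
      if ("Finland" %in% rec$countries[[r]] &&
          g %in% rec$genes[[r]] && ct %in% rec$cities[[r]])
        oracle <- oracle + 1L
    expect_equal(got[g, ct], oracle)
  }
})

test_that("Ward clustering merges identical profiles at height zero", {
  m <- cbind(Helsinki = c(5L, 3L, 1L), Tampere = c(5L, 3L, 1L),
             Oulu = c(0L, 0L, 9L))
  rownames(m) <- c("A", "B", "C")
  hc <- wardCluster(gcmFromMatrix(m))
  expect_equal(hc$height[1], 0)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("Helsinki", "Tampere"))
})

test_that("near-identical planted profiles merge first and heights rise", {
  m <- cbind(Helsinki = c(10L, 9L, 0L, 0L), Tampere = c(10L, 10L, 0L, 1L),
             Oulu = c(0L, 1L, 12L, 11L))
  rownames(m) <- c("g1", "g2", "g3", "g4")
  hc <- wardCluster(gcmFromMatrix(m))
  expect_equal(sort(hc$labels[-hc$merge[1, ]]), c("Helsinki", "Tampere"))
  expect_true(all(diff(hc$height) >= -1e-12))  # Ward heights non-decreasing
})

test_that("clustering is invariant to city input order", {
  set.seed(77)
  m <- matrix(rpois(6 * 5, 4), 6, 5,
              dimnames = list(sprintf("g%d", 1:6), sprintf("c%d", 1:5)))
  hc <- wardCluster(gcmFromMatrix(m))
  perm <- sample(5)
  hc2 <- wardCluster(gcmFromMatrix(m[, perm]))
  expect_equal(hc$height, hc2$height, tolerance = 1e-12)
  # two-group cut recovers the same partition regardless of order
  part <- function(h) {
    ct <- stats::cutree(h, 2)
    unname(lapply(split(names(ct), ct), sort)[order(
      vapply(split(names(ct), ct), function(s) sort(s)[1], character(1)))])
  }
  expect_equal(part(hc), part(hc2))
})

test_that("planted two-group city profiles are recovered exactly", {
  # group 1: cities dominated by the first gene block; group 2: the second.
  set.seed(55)
  block <- function(hi, lo) as.integer(c(rpois(4, hi), rpois(4, lo)))
  m <- cbind(a1 = block(60, 1), a2 = block(60, 1), a3 = block(60, 1),
             b1 = block(1, 60), b2 = block(1, 60))
  rownames(m) <- sprintf("g%d", 1:8)
  hc <- wardCluster(gcmFromMatrix(m))
  ct <- stats::cutree(hc, 2)
  planted <- c(a1 = 1L, a2 = 1L, a3 = 1L, b1 = 2L, b2 = 2L)
  # Rand index of 1: same partition up to label swap
  agree <- outer(ct, ct, "==") == outer(planted, planted, "==")
  expect_true(all(agree))
})

test_that("proportion rows sum to one and expose exclusivity", {
  m <- rbind(A = c(2L, 2L, 0L), B = c(3L, 0L, 0L))
  colnames(m) <- c("Helsinki", "Tampere", "Turku")
  p <- geneCityProportions(gcmFromMatrix(m))
  expect_equal(p["A", ], c(Helsinki = 0.5, Tampere = 0.5, Turku = 0))
  # a gene studied by a single city has proportion 1 there, 0 elsewhere
  expect_equal(p["B", ], c(Helsinki = 1, Tampere = 0, Turku = 0))
  expect_equal(unname(rowSums(p)), rep(1, 2), tolerance = 1e-12)

  set.seed(5)
  mm <- matrix(rpois(30, 3) + 1L, 5, 6,
               dimnames = list(sprintf("g%d", 1:5), sprintf("c%d", 1:6)))
  expect_equal(unname(rowSums(geneCityProportions(gcmFromMatrix(mm)))),
               rep(1, 5), tolerance = 1e-12)

  zr <- rbind(A = c(1L, 1L), B = c(0L, 0L))
  colnames(zr) <- c("x", "y")
  expect_warning(p2 <- geneCityProportions(gcmFromMatrix(zr)), "B")
  expect_equal(rownames(p2), "A")
})

test_that("dendrograms export as parseable Newick with merge heights", {
  m <- cbind(Helsinki = c(5L, 0L), Tampere = c(4L, 1L), Oulu = c(0L, 7L))
  rownames(m) <- c("A", "B")
  hc <- wardCluster(gcmFromMatrix(m))
  f <- withr::local_tempfile(fileext = ".nwk")
  exportDendrogram(hc, f)
  phy <- ape::read.tree(f)
  expect_equal(sort(phy$tip.label), c("Helsinki", "Oulu", "Tampere"))
})
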