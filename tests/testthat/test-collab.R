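test_that("country matrix separates self-collaborations from pairs", {
  cp <- makeCorpus(countries = list("Finland"))
  m <- countryMatrix(cp)
  expect_equal(counts(m)["Finland", "Finland"], 1L)

  cp <- makeCorpus(countries = list(c("Finland", "United States")))
  m <- counts(countryMatrix(cp))
  expect_equal(m["Finland", "United States"], 1L)
  expect_equal(m["United States", "Finland"], 1L)
  expect_equal(diag(m), c(Finland = 0L, `United States` = 0L))
})

test_that("collaboration matrices match brute-force pair enumeration", {
  sim <- generateCorpus(syntheticSpec(nPubs = 50, seed = 13))
  cp <- annotateGeo(sim$corpus, focalCountry = "Finland")
  for (builder in list(
    function() list(countryMatrix(cp), records(cp)$countries),
    function() {
      keep <- vapply(records(cp)$countries, function(x) "Finland" %in% x,
                     logical(1))
      list(cityMatrix(cp, "Finland"), records(cp)$cities[keep])
    })) {
    built <- builder()
    got <- built[[1]]
    oracle <- bfCooccurrence(built[[2]])
    expect_equal(counts(got), oracle)
    expect_equal(entityTotals(got)[colnames(oracle)],
                 as.numeric(bfTotals(built[[2]])), ignore_attr = TRUE)
    # symmetry and nonnegative integer entries
    expect_identical(counts(got), t(counts(got)))
    expect_true(all(counts(got) >= 0))
  }
})

test_that("a three-city paper counts one collaboration per pair", {
  cp <- makeCorpus(countries = list("Finland", "Finland"),
                   cities = list(c("Helsinki", "Tampere", "Oulu"),
                                 "Helsinki"))
  m <- counts(cityMatrix(cp, "Finland"))
  expect_equal(m["Helsinki", "Tampere"], 1L)
  expect_equal(m["Helsinki", "Oulu"], 1L)
  expect_equal(m["Tampere", "Oulu"], 1L)
  # single-city paper (possibly several institutions) is one
  # self-collaboration on the diagonal
  expect_equal(m["Helsinki", "Helsinki"], 1L)
})

test_that("grouping low-volume countries into Others conserves counts", {
  m <- matrix(0L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m["a", "b"] <- m["b", "a"] <- 5L
  m["c", "d"] <- m["d", "c"] <- 1L
  m["a", "c"] <- m["c", "a"] <- 2L
  diag(m) <- c(10L, 8L, 1L, 0L)
  cm <- asCoocc(m, totals = c(a = 2000, b = 1500, c = 30, d = 20),
                semantics = "self_only_publications")

  g <- groupOthers(cm, minPubs = 1000)
  gm <- counts(g)
  expect_equal(sort(rownames(gm)), c("Others", "a", "b"))
  # hand enumeration: c-d pair (1) plus c,d diagonals (1 + 0) -> 2
  expect_equal(gm["Others", "Others"], 2L)
  expect_equal(gm["a", "Others"], 2L)
  expect_equal(gm["b", "Others"], 0L)
  expect_equal(gm["a", "b"], 5L)
  # conservation over unordered pairs incl. diagonal
  tot <- function(x) sum(x[upper.tri(x, diag = TRUE)])
  expect_equal(tot(gm), tot(m))
  expect_identical(gm, t(gm))

  # vacuous threshold and all-above-threshold leave the matrix unchanged
  expect_identical(counts(groupOthers(cm, minPubs = 0)), m)
  expect_identical(counts(groupOthers(cm, minPubs = 10)), m)
})

test_that("chord export emits each positive top-k pair once", {
  z <- asCoocc(matrix(0L, 2, 2, dimnames = list(c("A", "B"), c("A", "B"))),
               totals = c(A = 5, B = 3))
  expect_equal(nrow(chordExport(z, 2)), 0L)

  m <- matrix(c(0L, 5L, 5L, 0L), 2, dimnames = list(c("A", "B"), c("A", "B")))
  out <- chordExport(asCoocc(m, totals = c(A = 5, B = 5)), 2)
  expect_equal(out, data.frame(source = "A", target = "B", value = 5L))

  set.seed(8)
  n <- 6
  mm <- matrix(0L, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
  mm[upper.tri(mm)] <- rpois(n * (n - 1) / 2, 2)
  mm <- mm + t(mm)
  totals <- stats::setNames(rpois(n, 50), LETTERS[1:n])
  out <- chordExport(asCoocc(mm, totals = totals), 3)
  top <- names(sort(totals, decreasing = TRUE))[1:3]  # oracle: filter + sort
  oracle <- which(upper.tri(mm) & mm > 0, arr.ind = TRUE)
  oracle <- oracle[rownames(mm)[oracle[, 1]] %in% top &
                   colnames(mm)[oracle[, 2]] %in% top, , drop = FALSE]
  expect_equal(nrow(out), nrow(oracle))
  expect_lte(nrow(out), 3 * 2 / 2)
  for (r in seq_len(nrow(out)))
    expect_equal(out$value[r], mm[out$source[r], out$target[r]])
})

test_that("self-collaboration percentages reproduce worked values", {
  buildSelf <- function(total, self, country = "Finland") {
    makeCorpus(countries = c(
      replicate(self, country, simplify = FALSE),
      replicate(total - self, c(country, "Sweden"), simplify = FALSE)))
  }
  roundHalfUp <- function(x, d) sign(x) * floor(abs(x) * 10^d + 0.5) / 10^d
  expect_equal(roundHalfUp(selfCollaborationPct(buildSelf(736, 343),
                                                "Finland"), 1), 46.6)
  expect_equal(roundHalfUp(selfCollaborationPct(buildSelf(530, 402),
                                                "Finland"), 2), 75.85)
  expect_equal(selfCollaborationPct(buildSelf(10, 10), "Finland"), 100)
  expect_error(selfCollaborationPct(buildSelf(5, 5), "Norway"), "Norway")
})
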