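test_that("HS assignment uses a strict threshold", {
  w <- c(g1 = 5, g2 = 10, g3 = 20)
  lab <- assignAttributes(w, "g1", gamma = 10)
  expect_equal(lab$hs, c(FALSE, FALSE, TRUE))  # count == gamma is HS-no
  expect_equal(lab$city, c(TRUE, FALSE, FALSE))
  expect_true(all(assignAttributes(w, character(0), 0)$hs))
  expect_false(any(assignAttributes(w, character(0), 20)$hs))
  expect_error(assignAttributes(w, "absent", 0), "absent")
})

test_that("contingency cells and margins are consistent", {
  lab <- data.frame(hs = c(TRUE, TRUE, FALSE, FALSE),
                    city = c(TRUE, FALSE, TRUE, FALSE))
  tab <- buildContingency(lab)
  m <- contingencyMargins(tab)
  expect_equal(unname(m[c("x", "n12", "n21", "n22")]), c(1, 1, 1, 1))
  expect_equal(m[["nPlus1"]], m[["x"]] + m[["n21"]])
  expect_equal(m[["n1Plus"]], m[["x"]] + m[["n12"]])
  expect_equal(m[["n"]], m[["nPlus1"]] + m[["nPlus2"]])
  expect_equal(m[["n"]], m[["n1Plus"]] + m[["n2Plus"]])
  # permutation invariance and the empty table
  expect_equal(buildContingency(lab[sample(4), ]), tab)
  zero <- buildContingency(data.frame(hs = logical(0), city = logical(0)))
  expect_equal(contingencyMargins(zero)[["n"]], 0)
})

ctab <- function(x, n12, n21, n22)
  new("ContingencyTable", x = as.integer(x), n12 = as.integer(n12),
      n21 = as.integer(n21), n22 = as.integer(n22))

test_that("exact tail p-values match hand-derived values", {
  # n = 10, nPlus1 = 5, n1Plus = 4, x = 3: tail is the single term
  # P(4) = C(5,4) C(5,0) / C(10,4) = 5/210
  expect_equal(exactPvalue(ctab(3, 1, 2, 4)), 5 / 210, tolerance = 1e-12)
  # n = 6, nPlus1 = 3, n1Plus = 3, x = 1: P(2) + P(3) = (9 + 1)/20
  expect_equal(exactPvalue(ctab(1, 2, 2, 1)), 0.5, tolerance = 1e-12)
  # maximal overlap leaves an empty summation range
  expect_equal(exactPvalue(ctab(4, 0, 1, 5)), 0)
})

test_that("exact tail agrees with subset enumeration for all n <= 12", {
  for (n in 3:12) {
    for (nPlus1 in 1:(n - 1)) {
      for (n1Plus in 1:(n - 1)) {
        for (x in 0:min(nPlus1, n1Plus)) {
          n12 <- n1Plus - x
          n21 <- nPlus1 - x
          n22 <- n - x - n12 - n21
          if (n12 < 0 || n21 < 0 || n22 < 0) next
          expect_equal(exactPvalue(ctab(x, n12, n21, n22)),
                       enumPvalue(x, nPlus1, n1Plus, n),
                       tolerance = 1e-12,
                       label = sprintf("n=%d nPlus1=%d n1Plus=%d x=%d",
                                       n, nPlus1, n1Plus, x))
        }
      }
    }
  }
})

test_that("the sampling distribution sums to one over its support", {
  pointProb <- function(k, nPlus1, n, n1Plus)
    exp(lchoose(nPlus1, k) + lchoose(n - nPlus1, n1Plus - k) -
          lchoose(n, n1Plus))
  for (set in list(c(10, 4, 6), c(50, 20, 35), c(7519, 1078, 300))) {
    n <- set[1]; nPlus1 <- set[2]; n1Plus <- set[3]
    expect_equal(sum(pointProb(0:n1Plus, nPlus1, n, n1Plus)), 1,
                 tolerance = 1e-12)
  }
})

test_that("p-values are probabilities, non-increasing in x, phyper-consistent", {
  n <- 40; nPlus1 <- 12; n1Plus <- 15
  prev <- 1
  for (x in 0:min(nPlus1, n1Plus)) {
    n12 <- n1Plus - x; n21 <- nPlus1 - x; n22 <- n - x - n12 - n21
    if (n22 < 0) next
    p <- exactPvalue(ctab(x, n12, n21, n22))
    expect_gte(p, 0); expect_lte(p, 1)
    expect_lte(p, prev + 1e-12)
    prev <- p
    # independent check against the standard hypergeometric tail
    expect_equal(p, stats::phyper(x, nPlus1, n - nPlus1, n1Plus,
                                  lower.tail = FALSE), tolerance = 1e-12)
    expect_equal(exactPvalue(ctab(x, n12, n21, n22), includeObserved = TRUE),
                 stats::phyper(x - 1, nPlus1, n - nPlus1, n1Plus,
                               lower.tail = FALSE), tolerance = 1e-12)
  }
})

test_that("degenerate margins return p = 1 by convention", {
  expect_equal(exactPvalue(ctab(0, 0, 3, 7)), 1)   # no HS-yes gene
  expect_equal(exactPvalue(ctab(3, 7, 0, 0)), 1)   # every gene HS-yes
  expect_equal(exactPvalue(ctab(0, 10, 0, 0)), 1)  # no city gene
})

test_that("the sweep applies Bonferroni over the supplied thresholds", {
  w <- stats::setNames(c(50, 40, 30, 20, 10, 5, 4, 3, 2, 1),
                       sprintf("g%02d", 1:10))
  city <- c("g01", "g02", "g03")
  one <- enrichmentSweep(w, city, gammas = 25)
  expect_equal(one$significant, one$p_value < 0.05)  # divisor 1

  sw <- enrichmentSweep(w, city, gammas = c(0, 10, 25, 50))
  expect_equal(nrow(sw), 4L)
  expect_equal(sw$significant, sw$p_value < 0.05 / 4)
  # extremes: all genes selected (gamma 0 on an all-positive table) and
  # no gene selected (gamma >= max count) both give p = 1
  expect_equal(sw$p_value[sw$gamma == 0], 1)
  expect_equal(sw$p_value[sw$gamma == 50], 1)
  expect_error(enrichmentSweep(w, city, gammas = numeric(0)), "non-empty")
})
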