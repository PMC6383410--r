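# Exact enrichment of highly-studied genes in a city's gene set:
# attribute assignment, 2x2 contingency construction, the exact
# hypergeometric tail p-value (strict exclusion of the observed count),
# and a threshold sweep with Bonferroni correction.

#' Assign HS and City attributes to genes
#'
#' Every gene studied worldwide gets two binary attributes: \emph{HS}
#' ("highly studied") is yes iff its worldwide publication count is
#' strictly greater than the threshold \code{gamma}; \emph{City} is "in"
#' iff the gene belongs to the city's gene set.
#'
#' @param worldCounts named vector of worldwide per-gene publication
#'   counts.
#' @param cityGenes character vector of genes studied in the city; must be
#'   a subset of \code{names(worldCounts)}.
#' @param gamma nonnegative threshold (a gene with count equal to gamma is
#'   HS-no).
#' @return data.frame with columns \code{gene}, \code{hs}, \code{city}.
#' @export
assignAttributes <- function(worldCounts, cityGenes, gamma) {
  stopifnot(is.numeric(worldCounts), !is.null(names(worldCounts)))
  extra <- setdiff(cityGenes, names(worldCounts))
  if (length(extra))
    stop("city genes absent from the worldwide table: ",
         paste(extra, collapse = ", "), call. = FALSE)
  data.frame(gene = names(worldCounts),
             hs = unname(worldCounts) > gamma,
             city = names(worldCounts) %in% cityGenes,
             stringsAsFactors = FALSE)
}

#' Build the 2x2 enrichment contingency table
#'
#' @param labels data.frame from \code{\link{assignAttributes}} (columns
#'   \code{hs} and \code{city}).
#' @return A \code{\link{ContingencyTable}} with cells x (HS-yes/City-in),
#'   n12 (HS-yes/City-out), n21 (HS-no/City-in), n22 (HS-no/City-out).
#' @export
buildContingency <- function(labels) {
  stopifnot(all(c("hs", "city") %in% names(labels)))
  new("ContingencyTable",
      x = sum(labels$hs & labels$city),
      n12 = sum(labels$hs & !labels$city),
      n21 = sum(!labels$hs & labels$city),
      n22 = sum(!labels$hs & !labels$city))
}

#' Margins of a contingency table
#'
#' @param table a \code{\link{ContingencyTable}}.
#' @return Named vector with x, n12, n21, n22, the margins nPlus1 (city
#'   total), nPlus2, n1Plus (HS total), n2Plus, and the grand total n.
#' @export
contingencyMargins <- function(table) {
  x <- table@x; n12 <- table@n12; n21 <- table@n21; n22 <- table@n22
  c(x = x, n12 = n12, n21 = n21, n22 = n22,
    nPlus1 = x + n21, nPlus2 = n12 + n22,
    n1Plus = x + n12, n2Plus = n21 + n22,
    n = x + n12 + n21 + n22)
}

# Hypergeometric point probability in log-space:
# P(k) = C(nPlus1, k) C(n - nPlus1, n1Plus - k) / C(n, n1Plus).
# lchoose returns -Inf outside the support, so impossible k give 0.
hyperPointProb <- function(k, nPlus1, n, n1Plus) {
  exp(lchoose(nPlus1, k) + lchoose(n - nPlus1, n1Plus - k) -
        lchoose(n, n1Plus))
}

#' Exact enrichment p-value
#'
#' Exact tail probability of drawing more city genes among the highly
#' studied set than observed, under the hypergeometric null: with
#' \eqn{P(k) = \binom{n_{+1}}{k}\binom{n - n_{+1}}{n_{1+} - k} /
#' \binom{n}{n_{1+}}}, the p-value is \eqn{\sum_{k = x+1}^{n_{1+}} P(k)},
#' i.e. the observed count x is \emph{excluded} from the tail (strict
#' \eqn{k > x}). The conventional one-sided exact test includes the
#' observed table; set \code{includeObserved = TRUE} for that variant.
#' Computed in log-space via log binomial coefficients, so it is stable for
#' gene universes of thousands of genes. A degenerate table (any zero
#' margin, e.g. no HS-yes gene or all genes HS-yes) returns p = 1 by
#' convention, matching the behavior of the sweep at its extreme
#' thresholds.
#'
#' @param table a \code{\link{ContingencyTable}}.
#' @param includeObserved include the observed x in the tail (default
#'   FALSE, the strict convention).
#' @return p-value in [0, 1].
#' @export
exactPvalue <- function(table, includeObserved = FALSE) {
  m <- contingencyMargins(table)
  if (m["nPlus1"] == 0 || m["nPlus2"] == 0 ||
      m["n1Plus"] == 0 || m["n2Plus"] == 0)
    return(1)
  from <- if (includeObserved) m[["x"]] else m[["x"]] + 1L
  hi <- min(m[["n1Plus"]], m[["nPlus1"]])
  if (from > hi) return(0)
  ks <- seq.int(from, hi)
  p <- sum(hyperPointProb(ks, m[["nPlus1"]], m[["n"]], m[["n1Plus"]]))
  min(max(p, 0), 1)
}

#' Sweep the highly-studied threshold with Bonferroni correction
#'
#' Repeats the enrichment test over a user-supplied list of thresholds
#' \code{gammas}; each test is declared significant iff its p-value is
#' below \code{alpha / length(gammas)} (Bonferroni over the sweep). The
#' threshold list is taken exactly as given and never altered. At extreme
#' thresholds (no gene, or every gene, highly studied) the table is
#' degenerate and the p-value is 1.
#'
#' @param worldCounts named worldwide per-gene publication counts.
#' @param cityGenes genes studied in the city.
#' @param gammas integer thresholds to sweep (non-empty).
#' @param alpha family significance level (default 0.05).
#' @param includeObserved passed to \code{\link{exactPvalue}}.
#' @return data.frame with one row per gamma: gamma, x, n12, n21, n22,
#'   p_value, significant.
#' @export
enrichmentSweep <- function(worldCounts, cityGenes, gammas, alpha = 0.05,
                            includeObserved = FALSE) {
  if (!length(gammas)) stop("gammas must be non-empty", call. = FALSE)
  res <- lapply(gammas, function(g) {
    tab <- buildContingency(assignAttributes(worldCounts, cityGenes, g))
    m <- contingencyMargins(tab)
    data.frame(gamma = g, x = m[["x"]], n12 = m[["n12"]], n21 = m[["n21"]],
               n22 = m[["n22"]],
               p_value = exactPvalue(tab, includeObserved))
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_value < alpha / length(gammas)
  rownames(out) <- NULL
  out
}
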