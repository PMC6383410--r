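# Yearly share of genetics research per country, interval-pair slope
# regressions and Bonferroni adjustment.

#' Percentage of genetics research
#'
#' @param nGenetics number of genetics publications.
#' @param nTotal total number of publications (>= 1 and >= nGenetics).
#' @return 100 * nGenetics / nTotal at full precision; round only when
#'   reporting.
#' @examples
#' geneticsPercentage(1444, 2714)  # 53.2093...
#' @export
geneticsPercentage <- function(nGenetics, nTotal) {
  if (length(nTotal) != 1 || is.na(nTotal) || nTotal < 1)
    stop("nTotal must be a positive count", call. = FALSE)
  if (nGenetics > nTotal || nGenetics < 0)
    stop("nGenetics must lie in [0, nTotal]", call. = FALSE)
  100 * nGenetics / nTotal
}

#' Yearly genetics-share series for an entity
#'
#' For every year with at least one qualifying publication, computes the
#' percentage of genetics publications among the publications attributed to
#' the entity (a country, or \code{"all"} for the whole corpus). Years
#' without publications for the entity are omitted, not imputed as zero.
#' Each year is labeled with its time interval; years outside every
#' interval get \code{NA}.
#'
#' @param corpus a classified, located \code{\link{Corpus}}.
#' @param entity canonical country name, or \code{"all"}.
#' @param intervals named list of c(start, end) year pairs (defaults to
#'   A: 1987-1996, B: 1997-2006, C: 2007-2018).
#' @return data.frame with columns year, total, genetics, percentage,
#'   interval, plus an \code{"entity"} attribute.
#' @export
buildSeries <- function(corpus, entity = "all",
                        intervals = defaultIntervals()) {
  rec <- records(corpus)
  keep <- if (identical(entity, "all")) rep(TRUE, nrow(rec))
          else vapply(rec$countries, function(s) entity %in% s, logical(1))
  if (!any(keep))
    stop("no publications for entity: ", entity, call. = FALSE)
  isGen <- classifyGenetics(corpus)[keep]
  years <- rec$year[keep]
  yrs <- sort(unique(years))
  total <- vapply(yrs, function(y) sum(years == y), integer(1))
  gen <- vapply(yrs, function(y) sum(isGen[years == y]), integer(1))
  out <- data.frame(
    year = yrs, total = total, genetics = gen,
    percentage = vapply(seq_along(yrs), function(i)
      geneticsPercentage(gen[i], total[i]), numeric(1)),
    interval = vapply(yrs, intervalOfYear, character(1), intervals),
    stringsAsFactors = FALSE)
  attr(out, "entity") <- entity
  out
}

#' Interval-pair slope regression of the genetics share
#'
#' Ordinary least squares of the yearly percentages on an interval
#' indicator (first interval coded 0, second coded 1), so the slope equals
#' the difference of interval means; the p-value is the standard two-sided
#' t-test of the slope being zero. Each year contributes one unweighted
#' point.
#'
#' @param series data.frame from \code{\link{buildSeries}}.
#' @param pair length-2 character vector naming the two intervals, e.g.
#'   \code{c("A", "B")}.
#' @return List with entity, pair, beta1, p_value, n_points.
#' @export
intervalRegression <- function(series, pair = c("A", "B")) {
  stopifnot(length(pair) == 2)
  sub <- series[!is.na(series$interval) & series$interval %in% pair, ,
                drop = FALSE]
  nPer <- table(factor(sub$interval, levels = pair))
  if (any(nPer < 2))
    stop("need at least 2 yearly points in interval ",
         paste(pair[nPer < 2], collapse = " and "), call. = FALSE)
  indicator <- as.integer(sub$interval == pair[2])
  fit <- summary(stats::lm(sub$percentage ~ indicator))
  list(entity = attr(series, "entity"), pair = pair,
       beta1 = unname(fit$coefficients["indicator", "Estimate"]),
       p_value = unname(fit$coefficients["indicator", "Pr(>|t|)"]),
       n_points = nrow(sub))
}

#' Bonferroni significance over a family of tests
#'
#' @param pValues numeric vector of p-values (non-empty).
#' @param alpha family significance level.
#' @return Logical vector: \code{pValues < alpha / length(pValues)}.
#' @export
bonferroniSignificant <- function(pValues, alpha = 0.05) {
  if (!length(pValues)) stop("pValues must be non-empty", call. = FALSE)
  pValues < alpha / length(pValues)
}
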