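# Country- and city-level collaboration matrices, "Others" grouping,
# chord-diagram export and self-collaboration statistics.

# Build a symmetric co-occurrence matrix from per-record entity sets.
# Off-diagonal [i,j]: publications whose set contains both i and j (every
# unordered pair of a multi-entity paper counts once, regardless of author
# multiplicity). Diagonal: publications whose set is exactly {i}
# (self-collaborations). Totals: publications whose set contains i.
cooccurrenceFromSets <- function(sets) {
  sets <- lapply(sets, function(s) sort(unique(s)))
  labels <- sort(unique(unlist(sets)))
  m <- matrix(0L, length(labels), length(labels),
              dimnames = list(labels, labels))
  totals <- stats::setNames(integer(length(labels)), labels)
  for (s in sets) {
    if (!length(s)) next
    totals[s] <- totals[s] + 1L
    if (length(s) == 1L) {
      m[s, s] <- m[s, s] + 1L
    } else {
      pr <- utils::combn(s, 2)
      for (k in seq_len(ncol(pr))) {
        i <- pr[1, k]; j <- pr[2, k]
        m[i, j] <- m[i, j] + 1L
        m[j, i] <- m[j, i] + 1L
      }
    }
  }
  new("CooccurrenceMatrix", counts = m, totals = as.numeric(totals) |>
        stats::setNames(labels),
      diagonalSemantics = "self_only_publications")
}

#' Country collaboration matrix
#'
#' Symmetric matrix over the countries occurring in the corpus:
#' off-diagonal entries count publications whose resolved country set
#' contains both countries (a paper with three or more countries increments
#' every unordered pair once); the diagonal counts publications whose
#' country set is that single country (self-collaborations). Per-country
#' publication totals are carried separately (see
#' \code{\link{entityTotals}}) because for multi-country papers they are
#' not row sums.
#'
#' @param corpus a \code{\link{Corpus}} with countries extracted.
#' @return A \code{\link{CooccurrenceMatrix}}.
#' @export
countryMatrix <- function(corpus)
  cooccurrenceFromSets(records(corpus)$countries)

#' City collaboration matrix for the focal country
#'
#' As \code{\link{countryMatrix}}, over the deduplicated city sets of
#' publications attributed to the focal country: each unordered city pair
#' on a paper counts one collaboration, and a paper whose authors all sit
#' in one city (possibly at different institutions) counts one
#' self-collaboration on that city's diagonal.
#'
#' @param corpus a \code{\link{Corpus}} with cities extracted.
#' @param focalCountry country whose cities are analyzed; records not
#'   containing it are ignored.
#' @return A \code{\link{CooccurrenceMatrix}}.
#' @export
cityMatrix <- function(corpus, focalCountry = "Finland") {
  rec <- records(corpus)
  keep <- vapply(rec$countries, function(x) focalCountry %in% x, logical(1))
  cooccurrenceFromSets(rec$cities[keep])
}

#' Merge low-volume entities into an "Others" category
#'
#' All entities whose publication total is below \code{minPubs} are merged
#' into a single \code{"Others"} label; merged rows/columns are summed
#' element-wise, and the \code{"Others"} diagonal additionally absorbs the
#' pairwise counts among merged entities, so the total over unordered pairs
#' (upper triangle plus diagonal) is conserved.
#'
#' @param mat a \code{\link{CooccurrenceMatrix}}.
#' @param minPubs threshold on the per-entity publication total
#'   (entities with total < minPubs are grouped).
#' @param label name of the merged category.
#' @return A \code{\link{CooccurrenceMatrix}}.
#' @export
groupOthers <- function(mat, minPubs = 1000, label = "Others") {
  totals <- entityTotals(mat)
  m <- counts(mat)
  small <- names(totals)[totals < minPubs]
  if (!length(small)) return(mat)
  keep <- setdiff(rownames(m), small)
  newLabels <- c(keep, label)
  out <- matrix(0L, length(newLabels), length(newLabels),
                dimnames = list(newLabels, newLabels))
  out[keep, keep] <- m[keep, keep, drop = FALSE]
  if (length(keep)) {
    cross <- m[small, keep, drop = FALSE]
    merged <- colSums(cross)
    out[label, keep] <- merged
    out[keep, label] <- merged
  }
  block <- m[small, small, drop = FALSE]
  out[label, label] <- sum(diag(block)) + sum(block[upper.tri(block)])
  newTot <- c(totals[keep], sum(totals[small]))
  names(newTot) <- newLabels
  new("CooccurrenceMatrix", counts = out, totals = newTot,
      diagonalSemantics = diagonalSemantics(mat))
}

#' Export a co-occurrence matrix as a three-column chord table
#'
#' Emits one row per unordered pair among the top-\code{k} entities (ranked
#' by publication totals, ties broken lexicographically) whose joint count
#' is positive: columns \code{source}, \code{target}, \code{value}.
#'
#' @param mat a \code{\link{CooccurrenceMatrix}}.
#' @param k number of top entities to keep (at most the number of labels).
#' @param path optional CSV file to write.
#' @return data.frame with columns source, target, value.
#' @export
chordExport <- function(mat, k, path = NULL) {
  totals <- entityTotals(mat)
  k <- assertCount(k, "k")
  if (k > length(totals))
    stop("k exceeds the number of entities", call. = FALSE)
  top <- names(totals)[order(-totals, names(totals))][seq_len(k)]
  m <- counts(mat)[top, top, drop = FALSE]
  rows <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  out <- data.frame(source = rownames(m)[rows[, 1]],
                    target = colnames(m)[rows[, 2]],
                    value = as.integer(m[rows]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}

#' Self-collaboration percentage of a country
#'
#' Percentage of the publications involving a country whose resolved
#' country set is exactly that country, i.e. papers authored entirely
#' within it.
#'
#' @param corpus a \code{\link{Corpus}} with countries extracted.
#' @param country canonical country name.
#' @return Percentage in [0, 100] at full precision; round only for
#'   reporting.
#' @export
selfCollaborationPct <- function(corpus, country) {
  sets <- records(corpus)$countries
  within <- vapply(sets, function(s) country %in% s, logical(1))
  if (!any(within))
    stop("country not present in corpus: ", country, call. = FALSE)
  only <- vapply(sets, function(s) identical(unique(s), country), logical(1))
  100 * sum(only) / sum(within)
}

#' Write a labeled co-occurrence matrix as TSV
#'
#' @param mat a \code{\link{CooccurrenceMatrix}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCooccurrence <- function(mat, path) {
  utils::write.table(counts(mat), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
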