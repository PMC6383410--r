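# Corpus construction, I/O, genetics classification, per-gene counting and
# first-mention extraction.

newProvenanceStep <- function(step, dropped, detail = NULL) {
  s <- list(step = step, dropped = as.integer(dropped))
  if (!is.null(detail)) s$detail <- detail
  s
}

emptyRecords <- function() {
  data.frame(pub_id = character(0), year = integer(0),
             affiliations = I(list()), genes = I(list()),
             countries = I(list()), cities = I(list()),
             stringsAsFactors = FALSE)
}

#' Build a Corpus from record fields
#'
#' Low-level constructor; most users read a corpus from disk with
#' \code{\link{readCorpus}} or simulate one with
#' \code{\link{generateCorpus}}.
#'
#' @param pub_id character vector of unique publication identifiers.
#' @param year integer vector of publication years.
#' @param affiliations,genes,countries,cities lists of character vectors,
#'   one element per publication (each may be empty).
#' @param provenance list of filtering steps already applied.
#' @return A \code{\link{Corpus}} object.
#' @examples
#' Corpus(pub_id = c("p1", "p2"), year = c(1999L, 2001L),
#'        genes = list(c("KLK3", "AR"), character(0)))
#' @export
Corpus <- function(pub_id = character(0), year = integer(0),
                   affiliations = NULL, genes = NULL,
                   countries = NULL, cities = NULL, provenance = list()) {
  n <- length(pub_id)
  fill <- function(x) {
    if (is.null(x)) return(replicate(n, character(0), simplify = FALSE))
    stopifnot(is.list(x), length(x) == n)
    lapply(x, as.character)
  }
  rec <- data.frame(pub_id = as.character(pub_id),
                    year = as.integer(year), stringsAsFactors = FALSE)
  rec$affiliations <- fill(affiliations)
  rec$genes <- fill(genes)
  rec$countries <- fill(countries)
  rec$cities <- fill(cities)
  new("Corpus", records = rec, provenance = provenance)
}

parseRecordList <- function(recs, source) {
  getf <- function(r, f) if (is.null(r[[f]])) character(0) else as.character(r[[f]])
  ids <- vapply(recs, function(r) {
    if (is.null(r$pub_id) || !nzchar(as.character(r$pub_id)[1]))
      stop("record without pub_id in ", source, call. = FALSE)
    as.character(r$pub_id)[1]
  }, character(1))
  years <- suppressWarnings(vapply(recs, function(r)
    as.integer(as.character(r$year)[1])[1], integer(1)))
  keep <- !is.na(years)
  if (anyDuplicated(ids[keep]))
    stop("duplicate pub_id: ",
         paste(unique(ids[keep][duplicated(ids[keep])]), collapse = ", "),
         call. = FALSE)
  corp <- Corpus(
    pub_id = ids[keep], year = years[keep],
    affiliations = lapply(recs[keep], getf, "affiliations"),
    genes = lapply(recs[keep], getf, "genes"),
    countries = lapply(recs[keep], getf, "countries"),
    cities = lapply(recs[keep], getf, "cities"),
    provenance = list(newProvenanceStep(
      "ingest", sum(!keep),
      sprintf("records with missing/unparseable year dropped from %s", source))))
  corp
}

#' Read an annotated publication corpus
#'
#' Canonical format is JSONL: one JSON object per line with fields
#' \code{pub_id} (string), \code{year} (integer), \code{affiliations} and
#' \code{genes} (arrays of strings); \code{countries}/\code{cities} arrays
#' are read when present. CSV carries the same columns with list fields
#' joined by \code{";"}. Records whose year is missing or unparseable are
#' dropped and counted in the corpus provenance.
#'
#' @param path file to read.
#' @param format \code{"jsonl"} or \code{"csv"}.
#' @return A \code{\link{Corpus}}.
#' @seealso \code{\link{writeCorpus}}
#' @export
readCorpus <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read corpus file: ", path, call. = FALSE)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    split_ <- function(x) if (is.na(x) || !nzchar(x)) character(0)
                          else strsplit(x, ";", fixed = TRUE)[[1]]
    recs <- lapply(seq_len(nrow(df)), function(i) {
      r <- as.list(df[i, , drop = FALSE])
      for (f in intersect(c("affiliations", "genes", "countries", "cities"),
                          names(r)))
        r[[f]] <- split_(r[[f]])
      r
    })
  }
  parseRecordList(recs, path)
}

#' Write a corpus to disk
#'
#' Inverse of \code{\link{readCorpus}}: reading a written corpus reproduces
#' its records exactly.
#'
#' @param corpus a \code{\link{Corpus}}.
#' @param path output file.
#' @param format \code{"jsonl"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
writeCorpus <- function(corpus, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  rec <- records(corpus)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(rec)), function(i) {
      jsonlite::toJSON(list(
        pub_id = jsonlite::unbox(rec$pub_id[i]),
        year = jsonlite::unbox(rec$year[i]),
        affiliations = rec$affiliations[[i]],
        genes = rec$genes[[i]],
        countries = rec$countries[[i]],
        cities = rec$cities[[i]]))
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    join <- function(col) vapply(col, paste, character(1), collapse = ";")
    utils::write.csv(data.frame(
      pub_id = rec$pub_id, year = rec$year,
      affiliations = join(rec$affiliations), genes = join(rec$genes),
      countries = join(rec$countries), cities = join(rec$cities),
      stringsAsFactors = FALSE), path, row.names = FALSE)
  }
  invisible(path)
}

#' Classify publications as genetics research
#'
#' A publication counts as genetics research iff its deduplicated gene set
#' is non-empty, i.e. the abstract annotation mentions at least one gene.
#' Publications without gene annotations are legitimate records (e.g.
#' survival or quality-of-life studies) classified as non-genetics.
#'
#' @param corpus a \code{\link{Corpus}}.
#' @return Logical vector, one element per record.
#' @examples
#' cp <- Corpus(pub_id = c("a", "b"), year = c(2000L, 2000L),
#'              genes = list(c("AR", "AR"), character(0)))
#' classifyGenetics(cp)  # TRUE FALSE
#' @export
classifyGenetics <- function(corpus) {
  vapply(records(corpus)$genes,
         function(g) length(unique(g)) > 0, logical(1))
}

geneSets <- function(corpus) lapply(records(corpus)$genes, unique)

#' Per-gene publication counts
#'
#' Counts, for every gene, the publications whose deduplicated gene set
#' contains it (default), or raw mentions when \code{unit = "mentions"}.
#' With \code{byYear = TRUE} a gene-by-year matrix is returned whose row
#' sums equal the aggregate counts.
#'
#' @param corpus a non-empty \code{\link{Corpus}}.
#' @param byYear return a gene x year matrix instead of a vector.
#' @param unit \code{"publications"} (per-publication dedup, default) or
#'   \code{"mentions"} (raw mention count).
#' @return Named integer vector sorted by decreasing count (ties by symbol),
#'   or an integer matrix with genes in rows and years in columns.
#' @export
genePublicationCounts <- function(corpus, byYear = FALSE,
                                  unit = c("publications", "mentions")) {
  unit <- match.arg(unit)
  if (length(corpus) == 0) stop("corpus is empty", call. = FALSE)
  rec <- records(corpus)
  sets <- if (unit == "publications") geneSets(corpus) else rec$genes
  genes <- unlist(sets, use.names = FALSE)
  if (byYear) {
    years <- rep(rec$year, lengths(sets))
    if (!length(genes))
      return(matrix(integer(0), 0, 0))
    tab <- table(gene = genes, year = years)
    m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
    return(m[order(-rowSums(m), rownames(m)), , drop = FALSE])
  }
  if (!length(genes)) return(stats::setNames(integer(0), character(0)))
  tab <- table(genes)
  out <- stats::setNames(as.integer(tab), names(tab))
  out[order(-out, names(out))]
}

#' First mention of a gene
#'
#' Returns the earliest year in which any publication mentions the gene,
#' together with the union of the resolved country sets of all publications
#' mentioning it in that year.
#'
#' @param corpus a \code{\link{Corpus}} with countries extracted.
#' @param gene gene symbol.
#' @return List with elements \code{year} (integer) and \code{countries}
#'   (character vector, sorted).
#' @export
firstMention <- function(corpus, gene) {
  stopifnot(isString(gene))
  rec <- records(corpus)
  hit <- vapply(geneSets(corpus), function(g) gene %in% g, logical(1))
  if (!any(hit)) stop("gene not found in corpus: ", gene, call. = FALSE)
  y0 <- min(rec$year[hit])
  ctry <- sort(unique(unlist(rec$countries[hit & rec$year == y0])))
  list(year = y0, countries = ctry)
}

#' Top-k genes by publication count
#'
#' @param geneCounts named count vector, e.g. from
#'   \code{\link{genePublicationCounts}}.
#' @param k number of genes to return; must not exceed the table size.
#' @return Character vector of k gene symbols, sorted by decreasing count
#'   with ties broken lexicographically by symbol.
#' @export
topGenes <- function(geneCounts, k) {
  k <- assertCount(k, "k")
  if (k > length(geneCounts))
    stop(sprintf("k = %d exceeds the number of genes (%d)",
                 k, length(geneCounts)), call. = FALSE)
  names(geneCounts)[order(-geneCounts, names(geneCounts))][seq_len(k)]
}

#' Write a gene-count table as TSV
#'
#' @param geneCounts named count vector.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGeneCounts <- function(geneCounts, path) {
  utils::write.table(
    data.frame(gene = names(geneCounts), count = as.integer(geneCounts)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

addProvenance <- function(corpus, step) {
  new("Corpus", records = records(corpus),
      provenance = c(provenance(corpus), list(step)))
}
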