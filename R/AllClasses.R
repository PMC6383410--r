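#' @import methods
NULL

#' Corpus of annotated publication records
#'
#' A \code{Corpus} holds one row per publication. The columns of
#' \code{records} are \code{pub_id} (character), \code{year} (integer) and the
#' list-columns \code{affiliations} (raw affiliation strings), \code{genes}
#' (gene symbols as mentioned, possibly with repeats), \code{countries}
#' (canonical country names filled by \code{\link{annotateGeo}}) and
#' \code{cities} (focal-country cities). All counting operations use the
#' per-publication deduplicated gene set; the \code{genes} column keeps raw
#' mentions. \code{provenance} is a list of filtering steps, each recording
#' how many records the step dropped.
#'
#' @slot records data.frame with the columns described above.
#' @slot provenance list of steps, each a list with elements \code{step},
#'   \code{dropped} and optionally \code{detail}.
#'
#' @seealso \code{\link{readCorpus}}, \code{\link{annotateGeo}}
#' @export
setClass("Corpus",
  slots = c(records = "data.frame", provenance = "list"))

setValidity("Corpus", function(object) {
  rec <- object@records
  need <- c("pub_id", "year", "affiliations", "genes", "countries", "cities")
  if (!all(need %in% names(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(rec$pub_id)) {
    dup <- unique(rec$pub_id[duplicated(rec$pub_id)])
    return(sprintf("duplicate pub_id: %s", paste(dup, collapse = ", ")))
  }
  if (nrow(rec) > 0 && (!is.numeric(rec$year) || anyNA(rec$year)))
    return("year must be numeric and non-missing for every record")
  for (col in c("affiliations", "genes", "countries", "cities"))
    if (!is.list(rec[[col]]))
      return(sprintf("column '%s' must be a list-column", col))
  TRUE
})

#' Symmetric co-occurrence matrix of joint publication counts
#'
#' Labeled square matrix counting, for each unordered pair of entities
#' (countries, cities or genes), the number of publications on which both
#' occur. The diagonal carries one of two meanings, recorded in
#' \code{diagonalSemantics}: \code{"self_only_publications"} (collaboration
#' matrices: the diagonal counts publications whose entity set is exactly
#' that singleton, i.e. self-collaborations) or
#' \code{"entity_publication_total"} (gene matrices: the diagonal is the
#' per-gene publication count and is excluded from thresholding).
#' Per-entity publication totals (publications whose entity set contains the
#' entity) are kept separately in \code{totals} because for multi-entity
#' publications they are not row sums of the matrix.
#'
#' @slot counts square symmetric matrix of nonnegative integers with
#'   identical row/column dimnames.
#' @slot totals named integer vector of per-entity publication totals.
#' @slot diagonalSemantics either \code{"self_only_publications"} or
#'   \code{"entity_publication_total"}.
#'
#' @seealso \code{\link{countryMatrix}}, \code{\link{geneMatrix}},
#'   \code{\link{cityMatrix}}
#' @export
setClass("CooccurrenceMatrix",
  slots = c(counts = "matrix", totals = "numeric",
            diagonalSemantics = "character"))

setValidity("CooccurrenceMatrix", function(object) {
  m <- object@counts
  if (nrow(m) != ncol(m)) return("counts must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("counts must carry identical row and column names")
  if (anyDuplicated(rownames(m))) return("entity labels must be unique")
  if (length(m) && (anyNA(m) || any(m < 0) || any(m != round(m))))
    return("counts must be nonnegative integers")
  if (length(m) && !isTRUE(all.equal(m, t(m))))
    return("counts must be symmetric")
  if (!identical(sort(names(object@totals)), sort(rownames(m))))
    return("totals must be named by the same entities as counts")
  if (!object@diagonalSemantics %in%
      c("self_only_publications", "entity_publication_total"))
    return("unknown diagonalSemantics")
  TRUE
})

#' Thresholded co-occurrence graph
#'
#' Unweighted graph obtained by keeping an edge wherever the off-diagonal
#' joint-publication count strictly exceeds the threshold \eqn{\Theta}:
#' \eqn{B_{ij} = 1} if \eqn{A_{ij} > \Theta}, else 0. Labels with no
#' surviving edge are retained in \code{labels} as isolated vertices.
#' \code{weights} keeps the originating joint counts for export.
#'
#' @slot labels character vector of all entity labels.
#' @slot edges two-column character matrix of unordered pairs (each pair
#'   stored once, lexicographically ordered within the row).
#' @slot weights numeric vector of joint counts parallel to \code{edges}.
#' @slot theta the threshold used.
#'
#' @seealso \code{\link{thresholdGraph}}, \code{\link{graphCommunities}}
#' @export
setClass("ThresholdedGraph",
  slots = c(labels = "character", edges = "matrix", weights = "numeric",
            theta = "numeric"))

setValidity("ThresholdedGraph", function(object) {
  e <- object@edges
  if (ncol(e) != 2 && length(e) > 0) return("edges must have two columns")
  if (nrow(e) != length(object@weights))
    return("weights must parallel edges")
  if (nrow(e)) {
    if (any(e[, 1] == e[, 2])) return("self-loops are not allowed")
    if (!all(e %in% object@labels)) return("edge endpoints must be labels")
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    if (anyDuplicated(key)) return("duplicate edges")
  }
  if (object@theta < 0) return("theta must be nonnegative")
  TRUE
})

#' 2x2 contingency table for the literature enrichment test
#'
#' Cross-classifies genes by the two attributes used in the enrichment
#' analysis: \emph{HS} (highly studied worldwide: publication count strictly
#' above a threshold \eqn{\gamma}) and \emph{City} (studied in the focal
#' city). Cells: \code{x} = HS-yes & City-in, \code{n12} = HS-yes & City-out,
#' \code{n21} = HS-no & City-in, \code{n22} = HS-no & City-out. Margins are
#' derived: column totals \eqn{n_{+1} = x + n_{21}} (genes studied in the
#' city) and \eqn{n_{+2} = n_{12} + n_{22}}; row totals
#' \eqn{n_{1+} = x + n_{12}} (highly studied genes) and
#' \eqn{n_{2+} = n_{21} + n_{22}}; \eqn{n} the total number of genes.
#'
#' @slot x,n12,n21,n22 nonnegative integer cell counts.
#'
#' @seealso \code{\link{buildContingency}}, \code{\link{exactPvalue}}
#' @export
setClass("ContingencyTable",
  slots = c(x = "integer", n12 = "integer", n21 = "integer", n22 = "integer"))

setValidity("ContingencyTable", function(object) {
  v <- c(object@x, object@n12, object@n21, object@n22)
  if (length(v) != 4 || anyNA(v) || any(v < 0))
    return("all four cells must be single nonnegative integers")
  TRUE
})

#' Gene-by-city publication count matrix
#'
#' \code{counts[i, j]} is the number of publications whose gene set contains
#' gene \code{i} and whose (focal-country) city set contains city \code{j};
#' a multi-city publication counts once per city.
#'
#' @slot counts integer matrix, genes in rows, cities in columns, with
#'   unique dimnames.
#'
#' @seealso \code{\link{geneCityMatrix}}, \code{\link{wardCluster}}
#' @export
setClass("GeneCityMatrix", slots = c(counts = "matrix"))

setValidity("GeneCityMatrix", function(object) {
  m <- object@counts
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("counts must have gene row names and city column names")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    return("row/column labels must be unique")
  if (length(m) && (anyNA(m) || any(m < 0) || any(m != round(m))))
    return("counts must be nonnegative integers")
  TRUE
})

#' Gazetteer for affiliation-to-place resolution
#'
#' Lookup tables for resolving raw affiliation text to canonical countries
#' and (within one focal country) cities. \code{lookup} maps normalized
#' country names, aliases and US state names/abbreviations to canonical
#' country names; \code{cities} maps normalized city names to canonical city
#' names. Lookup keys are normalized case- and punctuation-insensitively,
#' so \code{"finland."} and \code{"Finland"} resolve identically.
#'
#' @slot lookup named character vector: normalized key -> canonical country.
#' @slot cities named character vector: normalized key -> canonical city.
#' @slot source description of where the tables came from.
#'
#' @seealso \code{\link{readGazetteer}}, \code{\link{extractCountries}}
#' @export
setClass("Gazetteer",
  slots = c(lookup = "character", cities = "character", source = "character"))

setValidity("Gazetteer", function(object) {
  if (is.null(names(object@lookup)) || anyDuplicated(names(object@lookup)))
    return("lookup keys must be unique and named")
  if (length(object@cities) &&
      (is.null(names(object@cities)) || anyDuplicated(names(object@cities))))
    return("city keys must be unique and named")
  TRUE
})

#' Specification of a synthetic annotated corpus
#'
#' Parameters of the synthetic corpus generator; see
#' \code{\link{syntheticSpec}} for defaults and the meaning of each field,
#' and \code{\link{generateCorpus}} for the sampling model.
#'
#' @slot nPubs number of publications.
#' @slot yearRange integer vector (start, end).
#' @slot countryWeights named probability vector over countries (sums to 1).
#' @slot pInternational probability a publication involves 2+ countries.
#' @slot nGenes gene vocabulary size.
#' @slot zipfExponent positive exponent of the Zipf popularity law.
#' @slot genesPerPub mean gene count for genetics publications (shifted
#'   Poisson, minimum 1).
#' @slot geneticsFractionByInterval named probability vector, one entry per
#'   time interval.
#' @slot intervals named list of c(start, end) year pairs defining the
#'   intervals.
#' @slot focalCountry country for which cities are generated.
#' @slot cityWeights named probability vector over focal-country cities.
#' @slot pMultiCity probability a focal-country publication spans 2 cities.
#' @slot nUnlocatable number of records given institution-only (unmatchable)
#'   affiliations.
#' @slot plantedEnrichedCityGenes genes over-sampled into focal-city records.
#' @slot seed master seed; the same seed and spec give a byte-identical
#'   corpus.
#'
#' @export
setClass("SyntheticSpec",
  slots = c(nPubs = "integer", yearRange = "integer",
            countryWeights = "numeric", pInternational = "numeric",
            nGenes = "integer", zipfExponent = "numeric",
            genesPerPub = "numeric", geneticsFractionByInterval = "numeric",
            intervals = "list", focalCountry = "character",
            cityWeights = "numeric", pMultiCity = "numeric",
            nUnlocatable = "integer",
            plantedEnrichedCityGenes = "character", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  bad <- character(0)
  chk01 <- function(x) all(x >= 0 & x <= 1)
  if (object@nPubs < 0) bad <- c(bad, "nPubs")
  if (length(object@yearRange) != 2 || diff(object@yearRange) < 0)
    bad <- c(bad, "yearRange")
  if (abs(sum(object@countryWeights) - 1) > 1e-9 ||
      !chk01(object@countryWeights) || is.null(names(object@countryWeights)))
    bad <- c(bad, "countryWeights")
  if (!chk01(object@pInternational)) bad <- c(bad, "pInternational")
  if (object@nGenes < 1) bad <- c(bad, "nGenes")
  if (object@zipfExponent <= 0) bad <- c(bad, "zipfExponent")
  if (object@genesPerPub < 1) bad <- c(bad, "genesPerPub")
  if (!chk01(object@geneticsFractionByInterval) ||
      is.null(names(object@geneticsFractionByInterval)))
    bad <- c(bad, "geneticsFractionByInterval")
  if (!setequal(names(object@intervals),
                names(object@geneticsFractionByInterval)))
    bad <- c(bad, "intervals")
  if (length(object@cityWeights) &&
      (abs(sum(object@cityWeights) - 1) > 1e-9 || !chk01(object@cityWeights)))
    bad <- c(bad, "cityWeights")
  if (!chk01(object@pMultiCity)) bad <- c(bad, "pMultiCity")
  if (object@nUnlocatable < 0 || object@nUnlocatable > object@nPubs)
    bad <- c(bad, "nUnlocatable")
  if (length(bad)) return(paste("invalid fields:", paste(bad, collapse = ", ")))
  TRUE
})
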