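#' @importFrom BiocGenerics counts
NULL

#' Accessors for litscape classes
#'
#' \code{records} returns the record data.frame of a \code{\link{Corpus}};
#' \code{provenance} its filtering history. \code{counts} (the BiocGenerics
#' generic) returns the raw count matrix of a
#' \code{\link{CooccurrenceMatrix}} or \code{\link{GeneCityMatrix}};
#' \code{entityTotals} the per-entity publication totals;
#' \code{diagonalSemantics} the meaning of the diagonal.
#' \code{graphEdges}, \code{graphLabels} and \code{theta} access a
#' \code{\link{ThresholdedGraph}}.
#'
#' @param object a litscape S4 object.
#' @return The slot contents described above.
#' @name accessors
#' @aliases records provenance entityTotals diagonalSemantics graphEdges
#'   graphLabels theta counts,CooccurrenceMatrix-method
#'   counts,GeneCityMatrix-method
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(object) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("entityTotals", function(object) standardGeneric("entityTotals"))

#' @rdname accessors
#' @export
setGeneric("diagonalSemantics",
           function(object) standardGeneric("diagonalSemantics"))

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))

#' @rdname accessors
#' @export
setGeneric("graphLabels", function(object) standardGeneric("graphLabels"))

#' @rdname accessors
#' @export
setGeneric("theta", function(object) standardGeneric("theta"))

#' @rdname accessors
#' @export
setMethod("records", "Corpus", function(object) object@records)

#' @rdname accessors
#' @export
setMethod("provenance", "Corpus", function(object) object@provenance)

#' @rdname accessors
#' @export
setMethod("counts", "CooccurrenceMatrix", function(object, ...) object@counts)

#' @rdname accessors
#' @export
setMethod("counts", "GeneCityMatrix", function(object, ...) object@counts)

#' @rdname accessors
#' @export
setMethod("entityTotals", "CooccurrenceMatrix", function(object) object@totals)

#' @rdname accessors
#' @export
setMethod("diagonalSemantics", "CooccurrenceMatrix",
          function(object) object@diagonalSemantics)

#' @rdname accessors
#' @export
setMethod("graphEdges", "ThresholdedGraph", function(object) object@edges)

#' @rdname accessors
#' @export
setMethod("graphLabels", "ThresholdedGraph", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("theta", "ThresholdedGraph", function(object) object@theta)

#' @describeIn accessors number of records in the corpus.
#' @export
setMethod("length", "Corpus", function(x) nrow(x@records))

setMethod("show", "Corpus", function(object) {
  rec <- object@records
  nGeo <- sum(lengths(rec$countries) > 0)
  cat(sprintf("Corpus with %d record(s)\n", nrow(rec)))
  if (nrow(rec))
    cat(sprintf("  years: %d-%d | located: %d | with gene annotations: %d\n",
                min(rec$year), max(rec$year), nGeo,
                sum(lengths(lapply(rec$genes, unique)) > 0)))
  if (length(object@provenance)) {
    steps <- vapply(object@provenance, function(s)
      sprintf("%s (dropped %d)", s$step, s$dropped), character(1))
    cat("  provenance:", paste(steps, collapse = " -> "), "\n")
  }
})

setMethod("show", "CooccurrenceMatrix", function(object) {
  cat(sprintf("CooccurrenceMatrix: %d entities, diagonal = %s\n",
              nrow(object@counts), object@diagonalSemantics))
  off <- object@counts
  diag(off) <- 0
  cat(sprintf("  co-occurring pairs: %d | max joint count: %s\n",
              sum(off[upper.tri(off)] > 0),
              if (length(off)) max(off) else 0))
})

setMethod("show", "ThresholdedGraph", function(object) {
  cat(sprintf(
    "ThresholdedGraph: %d labels, %d edges at theta = %g (strict >)\n",
    length(object@labels), nrow(object@edges), object@theta))
})

setMethod("show", "ContingencyTable", function(object) {
  m <- matrix(c(object@x, object@n12, object@n21, object@n22),
              2, 2, byrow = TRUE,
              dimnames = list(c("HS-yes", "HS-no"), c("City-in", "City-out")))
  cat("ContingencyTable (n =", sum(m), ")\n")
  print(m)
})

setMethod("show", "GeneCityMatrix", function(object) {
  cat(sprintf("GeneCityMatrix: %d genes x %d cities, total count %d\n",
              nrow(object@counts), ncol(object@counts), sum(object@counts)))
})

setMethod("show", "Gazetteer", function(object) {
  cat(sprintf("Gazetteer: %d country keys, %d city keys (%s)\n",
              length(object@lookup), length(object@cities), object@source))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(paste0(
    "SyntheticSpec: %d pubs, years %d-%d, %d genes (zipf %.2f), ",
    "%d countries, focal %s, seed %d\n"),
    object@nPubs, object@yearRange[1], object@yearRange[2], object@nGenes,
    object@zipfExponent, length(object@countryWeights), object@focalCountry,
    object@seed))
})
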