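# Gene-by-city count matrix, Ward/Euclidean clustering of cities and
# per-gene city proportions.

#' Gene-by-city publication count matrix
#'
#' \code{counts[i, j]} is the number of publications whose deduplicated
#' gene set contains gene i and whose city set contains city j; a
#' multi-city publication counts once per city.
#'
#' @param corpus a \code{\link{Corpus}} with cities extracted.
#' @param topGenes non-empty character vector of the genes to keep as rows
#'   (e.g. the top 19 genes worldwide).
#' @param focalCountry restrict to publications attributed to this country.
#' @return A \code{\link{GeneCityMatrix}}.
#' @export
geneCityMatrix <- function(corpus, topGenes, focalCountry = "Finland") {
  stopifnot(length(topGenes) > 0)
  rec <- records(corpus)
  keep <- vapply(rec$countries, function(s) focalCountry %in% s, logical(1))
  sets <- lapply(rec$genes[keep], unique)
  citySets <- lapply(rec$cities[keep], unique)
  cities <- sort(unique(unlist(citySets)))
  m <- matrix(0L, length(topGenes), length(cities),
              dimnames = list(topGenes, cities))
  for (r in seq_along(sets)) {
    g <- intersect(sets[[r]], topGenes)
    ct <- citySets[[r]]
    if (length(g) && length(ct))
      m[g, ct] <- m[g, ct] + 1L
  }
  new("GeneCityMatrix", counts = m)
}

#' Ward clustering of cities by their gene profiles
#'
#' Agglomerative hierarchical clustering of the city column vectors using
#' Euclidean distance and Ward's minimum-variance linkage (the
#' squared-Euclidean "Ward.D2" update of the Lance-Williams recursion,
#' i.e. \code{stats::hclust(method = "ward.D2")} on a Euclidean
#' \code{dist}). Raw counts are clustered; columns are not standardized.
#' The result is deterministic given the matrix, and permuting the city
#' input order changes leaf order only, never merge heights.
#'
#' @param mat a \code{\link{GeneCityMatrix}} with at least 2 cities.
#' @return An \code{\link[stats]{hclust}} object over the cities.
#' @export
wardCluster <- function(mat) {
  m <- counts(mat)
  if (ncol(m) < 2)
    stop("need at least 2 cities to cluster", call. = FALSE)
  stats::hclust(stats::dist(t(m), method = "euclidean"), method = "ward.D2")
}

#' Per-gene city proportions
#'
#' Row-normalizes the gene-by-city matrix so each gene's row gives the
#' proportion of its publications contributed by each city (rows sum to 1).
#' Genes with no publications in any city are dropped with a warning.
#'
#' @param mat a \code{\link{GeneCityMatrix}}.
#' @return Numeric matrix of proportions with the same dimnames (minus any
#'   dropped zero rows).
#' @export
geneCityProportions <- function(mat) {
  m <- counts(mat)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    warning("dropping gene(s) with zero city counts: ",
            paste(rownames(m)[tot == 0], collapse = ", "))
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  sweep(m, 1, tot, "/")
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths reflect the merge heights of the clustering.
#'
#' @param hc an \code{\link[stats]{hclust}} object, e.g. from
#'   \code{\link{wardCluster}}.
#' @param path optional file to write.
#' @return The Newick string, invisibly if \code{path} is given.
#' @export
exportDendrogram <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
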