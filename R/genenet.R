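# Gene-gene literature co-occurrence matrix, strict thresholding,
# threshold-justification exceedance probability, communities and export.

#' Gene-gene literature co-occurrence matrix
#'
#' \code{A[i, j]} counts the publications whose deduplicated gene set
#' contains both gene i and gene j; the diagonal carries the per-gene
#' publication count (\code{diagonalSemantics =
#' "entity_publication_total"}) and is excluded from thresholding.
#'
#' @param corpus a \code{\link{Corpus}}.
#' @param geneticsOnly restrict to genetics publications (the default; by
#'   the classification rule any record mentioning a gene is genetics, so
#'   this mainly guards corpora with external annotations).
#' @return A \code{\link{CooccurrenceMatrix}}.
#' @export
geneMatrix <- function(corpus, geneticsOnly = TRUE) {
  sets <- geneSets(corpus)
  if (geneticsOnly) sets <- sets[lengths(sets) > 0]
  labels <- sort(unique(unlist(sets)))
  m <- matrix(0L, length(labels), length(labels),
              dimnames = list(labels, labels))
  totals <- stats::setNames(integer(length(labels)), labels)
  for (s in sets) {
    s <- sort(s)
    totals[s] <- totals[s] + 1L
    m[cbind(s, s)] <- m[cbind(s, s)] + 1L
    if (length(s) > 1) {
      pr <- utils::combn(s, 2)
      for (k in seq_len(ncol(pr))) {
        i <- pr[1, k]; j <- pr[2, k]
        m[i, j] <- m[i, j] + 1L
        m[j, i] <- m[j, i] + 1L
      }
    }
  }
  new("CooccurrenceMatrix", counts = m,
      totals = stats::setNames(as.numeric(totals), labels),
      diagonalSemantics = "entity_publication_total")
}

#' Threshold a co-occurrence matrix into an unweighted graph
#'
#' Keeps an edge (i, j) exactly where the off-diagonal joint count is
#' strictly greater than \code{theta} (\eqn{B_{ij} = 1} iff
#' \eqn{A_{ij} > \Theta}); the diagonal is ignored and labels without any
#' surviving edge are retained as isolated vertices.
#'
#' @param mat a \code{\link{CooccurrenceMatrix}}.
#' @param theta nonnegative threshold (default 10: an edge needs more than
#'   10 joint publications).
#' @return A \code{\link{ThresholdedGraph}}.
#' @export
thresholdGraph <- function(mat, theta = 10) {
  if (!is.numeric(theta) || length(theta) != 1 || theta < 0)
    stop("theta must be a single nonnegative number", call. = FALSE)
  m <- counts(mat)
  idx <- which(upper.tri(m) & m > theta, arr.ind = TRUE)
  edges <- cbind(rownames(m)[idx[, 1]], colnames(m)[idx[, 2]])
  if (!nrow(idx)) edges <- matrix(character(0), 0, 2)
  ord <- order(edges[, 1], edges[, 2])
  new("ThresholdedGraph", labels = rownames(m),
      edges = edges[ord, , drop = FALSE],
      weights = as.numeric(m[idx][ord]), theta = as.numeric(theta))
}

#' Exceedance probability of the joint-count threshold
#'
#' Empirical probability, over the unordered gene pairs that co-occur at
#' least once, that the joint-publication count strictly exceeds
#' \code{theta}. This is the quantity used to argue that a threshold is
#' conservative (e.g. a pair of genes being jointly studied in more than 10
#' publications having probability below 0.0005).
#'
#' @param mat a \code{\link{CooccurrenceMatrix}} of gene joint counts.
#' @param theta threshold.
#' @return Probability in [0, 1].
#' @export
pairExceedanceProbability <- function(mat, theta) {
  m <- counts(mat)
  pairCounts <- m[upper.tri(m)]
  pairCounts <- pairCounts[pairCounts >= 1]
  if (!length(pairCounts))
    stop("no co-occurring gene pairs; exceedance probability is undefined",
         call. = FALSE)
  mean(pairCounts > theta)
}

graphAsIgraph <- function(graph, includeIsolated = TRUE) {
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(if (includeIsolated) graphLabels(graph)
                     else sort(unique(as.vector(graphEdges(graph)))))
  e <- graphEdges(graph)
  if (nrow(e))
    g <- igraph::add_edges(g, as.vector(t(e)),
                           attr = list(weight = graph@weights))
  g
}

#' Communities of a thresholded gene network
#'
#' With \code{method = "components"} (the default) communities are the
#' connected components of the edge-bearing subgraph: isolated genes are
#' excluded and components are returned in decreasing size (ties broken by
#' first label), which is deterministic. A modularity-based alternative
#' (greedy modularity optimization) is available but non-default.
#'
#' @param graph a \code{\link{ThresholdedGraph}}.
#' @param method \code{"components"} or \code{"modularity"}.
#' @return List of character vectors (sorted gene symbols), one per
#'   community.
#' @export
graphCommunities <- function(graph, method = c("components", "modularity")) {
  method <- match.arg(method)
  if (!nrow(graphEdges(graph))) return(list())
  g <- graphAsIgraph(graph, includeIsolated = FALSE)
  member <- if (method == "components") {
    igraph::components(g)$membership
  } else {
    igraph::membership(igraph::cluster_fast_greedy(g))
  }
  comm <- split(names(member), member)
  comm <- lapply(comm, sort)
  comm[order(-lengths(comm), vapply(comm, `[`, character(1), 1))] |>
    unname()
}

#' Export a thresholded graph
#'
#' \code{"edgelist"} writes a TSV with columns \code{source},
#' \code{target}, \code{count} (the joint-publication count behind each
#' edge); an empty graph yields a header-only file. \code{"graphml"}
#' serializes the full graph including isolated vertices via igraph.
#'
#' @param graph a \code{\link{ThresholdedGraph}}.
#' @param path output file.
#' @param format \code{"edgelist"} or \code{"graphml"}.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{importGraph}}
#' @export
exportGraph <- function(graph, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    e <- graphEdges(graph)
    df <- data.frame(source = e[, 1], target = e[, 2],
                     count = graph@weights, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- graphAsIgraph(graph)
    igraph::graph_attr(g, "theta") <- theta(graph)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a graph written by exportGraph
#'
#' @param path file written by \code{\link{exportGraph}}.
#' @param format \code{"edgelist"} or \code{"graphml"}.
#' @param theta threshold to record on the returned graph (edgelist files
#'   do not store it; graphml files do).
#' @return A \code{\link{ThresholdedGraph}}.
#' @export
importGraph <- function(path, format = c("edgelist", "graphml"), theta = 0) {
  format <- match.arg(format)
  if (format == "edgelist") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c("character", "character", "numeric"))
    labels <- sort(unique(c(df$source, df$target)))
    e <- cbind(pmin(df$source, df$target), pmax(df$source, df$target))
    if (!nrow(df)) e <- matrix(character(0), 0, 2)
    ord <- order(e[, 1], e[, 2])
    new("ThresholdedGraph", labels = labels, edges = e[ord, , drop = FALSE],
        weights = as.numeric(df$count[ord]), theta = as.numeric(theta))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    labels <- igraph::V(g)$name
    em <- igraph::as_edgelist(g)
    w <- if ("weight" %in% igraph::edge_attr_names(g))
      igraph::E(g)$weight else rep(1, nrow(em))
    e <- cbind(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
    if (!nrow(em)) e <- matrix(character(0), 0, 2)
    ord <- order(e[, 1], e[, 2])
    th <- igraph::graph_attr(g, "theta")
    new("ThresholdedGraph", labels = labels, edges = e[ord, , drop = FALSE],
        weights = as.numeric(w[ord]),
        theta = if (is.null(th)) as.numeric(theta) else as.numeric(th))
  }
}
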