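# Independent brute-force oracles and small fixture builders shared across
# the test files. The oracles deliberately use naive enumeration so they
# share no code path with the package implementation.

# Brute-force co-occurrence: double loop over all label pairs and all
# entity sets.
bfCooccurrence <- function(sets, diagonalSelfOnly = TRUE) {
  sets <- lapply(sets, unique)
  labels <- sort(unique(unlist(sets)))
  m <- matrix(0L, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (i in labels) for (j in labels) {
    if (i == j) {
      m[i, i] <- if (diagonalSelfOnly)
        sum(vapply(sets, function(s) identical(s[order(s)], i), logical(1)))
      else sum(vapply(sets, function(s) i %in% s, logical(1)))
    } else {
      m[i, j] <- sum(vapply(sets, function(s) i %in% s && j %in% s,
                            logical(1)))
    }
  }
  m
}

bfTotals <- function(sets) {
  sets <- lapply(sets, unique)
  labels <- sort(unique(unlist(sets)))
  vapply(labels, function(l)
    sum(vapply(sets, function(s) l %in% s, logical(1))), integer(1))
}

# Brute-force per-gene publication counts.
bfGeneCounts <- function(corpus) {
  sets <- lapply(records(corpus)$genes, unique)
  genes <- sort(unique(unlist(sets)))
  vapply(genes, function(g)
    sum(vapply(sets, function(s) g %in% s, logical(1))), integer(1))
}

# Exact enrichment tail by full subset enumeration: universe of n genes of
# which the first nPlus1 are "in the city"; draw all subsets of size n1Plus
# and count those overlapping the city genes in more than x elements.
enumPvalue <- function(x, nPlus1, n1Plus, n) {
  if (n1Plus == 0 || n1Plus == n || nPlus1 == 0 || nPlus1 == n) return(1)
  subsets <- utils::combn(n, n1Plus)
  overlap <- colSums(subsets <= nPlus1)
  mean(overlap > x)
}

# Connected components by breadth-first search over an edge matrix.
bfComponents <- function(edges) {
  verts <- sort(unique(as.vector(edges)))
  seen <- character(0)
  comps <- list()
  adj <- lapply(stats::setNames(verts, verts), function(v)
    unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])))
  for (v in verts) {
    if (v %in% seen) next
    queue <- v; comp <- character(0)
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (u %in% comp) next
      comp <- c(comp, u)
      queue <- c(queue, setdiff(adj[[u]], comp))
    }
    comp <- sort(comp)
    seen <- c(seen, comp)
    comps[[length(comps) + 1]] <- comp
  }
  comps[order(-lengths(comps), vapply(comps, `[`, character(1), 1))]
}

# Corpus with explicit per-record fields, for hand-built fixtures.
makeCorpus <- function(genes = NULL, countries = NULL, cities = NULL,
                       years = NULL, affiliations = NULL) {
  n <- max(length(genes), length(countries), length(cities), length(years),
           length(affiliations))
  Corpus(pub_id = sprintf("p%03d", seq_len(n)),
         year = if (is.null(years)) rep(2000L, n) else years,
         affiliations = affiliations, genes = genes,
         countries = countries, cities = cities)
}

# A co-occurrence matrix built directly from a symmetric count matrix.
asCoocc <- function(m, totals = NULL,
                    semantics = "entity_publication_total") {
  if (is.null(totals)) totals <- stats::setNames(diag(m), rownames(m))
  new("CooccurrenceMatrix", counts = m,
      totals = stats::setNames(as.numeric(totals), rownames(m)),
      diagonalSemantics = semantics)
}
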