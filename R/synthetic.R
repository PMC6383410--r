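# Synthetic annotated corpus generator with planted ground truth.
#
# The generator emulates the structural features of a large gene-annotated
# publication corpus: a Zipf (power-law) gene popularity distribution, a
# dominant-country country distribution with a long tail and occasional
# multi-country (international) papers, a share of genetics publications
# that rises between the early and middle time intervals and then levels
# off, and city assignment within one focal country. Affiliation strings
# are synthesized as "Institute, City, Country" so that the geo-extraction
# stage is exercised end to end.

defaultCountryWeights <- function() {
  w <- c("United States" = 0.40, "China" = 0.08, "United Kingdom" = 0.06,
         "Japan" = 0.055, "Germany" = 0.05, "Italy" = 0.04, "France" = 0.04,
         "Canada" = 0.035, "Australia" = 0.03, "Netherlands" = 0.025,
         "Spain" = 0.02, "Sweden" = 0.02, "Finland" = 0.06,
         "South Korea" = 0.02, "India" = 0.02, "Brazil" = 0.015,
         "Switzerland" = 0.015, "Denmark" = 0.01, "Norway" = 0.01,
         "Austria" = 0.005)
  w / sum(w)
}

# City weights proportional to the observed publication volumes of the
# seven Finnish cities active in this literature.
defaultCityWeights <- function() {
  w <- c(Helsinki = 180, Tampere = 165, Turku = 116, Oulu = 64,
         Kuopio = 58, Espoo = 12, "Jyväskylä" = 1)
  w / sum(w)
}

defaultIntervals <- function()
  list(A = c(1987L, 1996L), B = c(1997L, 2006L), C = c(2007L, 2018L))

#' Create a synthetic-corpus specification
#'
#' Defaults describe the study conditions the package is validated under:
#' 31 publication years split into the intervals A (1987-1996),
#' B (1997-2006) and C (2007-2018); a genetics share rising from 0.40 in A
#' to 0.58 in B and staying level at 0.57 in C; a dominant country holding
#' ~40\% of the literature with a long tail of smaller contributors and a
#' 15\% chance of an international (multi-country) paper; a 500-gene
#' vocabulary with Zipf-distributed popularity (exponent 1.5) and on
#' average 2.5 genes per genetics abstract; and city assignment inside
#' Finland with weights proportional to the cities' observed publication
#' volumes.
#'
#' @param nPubs number of publications to generate.
#' @param yearRange first and last publication year.
#' @param countryWeights named probabilities over countries (must sum to 1).
#' @param pInternational probability that a paper has a second (or, with a
#'   geometric tail, further) country.
#' @param nGenes gene vocabulary size.
#' @param zipfExponent exponent s of the popularity law p(rank) ~ rank^-s.
#' @param genesPerPub mean number of genes on a genetics abstract (shifted
#'   Poisson, minimum 1).
#' @param geneticsFractionByInterval named per-interval genetics shares.
#' @param intervals named list of c(start, end) years, same names as
#'   \code{geneticsFractionByInterval}.
#' @param focalCountry country whose papers receive cities.
#' @param cityWeights named probabilities over focal-country cities.
#' @param pMultiCity probability a focal-country paper spans two cities.
#' @param nUnlocatable number of records whose affiliations are replaced by
#'   institution-only strings that no gazetteer can resolve.
#' @param plantedEnrichedCityGenes gene symbols planted into focal-city
#'   records to create genuine city enrichment.
#' @param seed master seed; identical spec and seed give a byte-identical
#'   corpus.
#' @return A validated \code{\link{SyntheticSpec}}.
#' @export
syntheticSpec <- function(nPubs = 5000,
                          yearRange = c(1987L, 2018L),
                          countryWeights = defaultCountryWeights(),
                          pInternational = 0.15,
                          nGenes = 500,
                          zipfExponent = 1.5,
                          genesPerPub = 2.5,
                          geneticsFractionByInterval =
                            c(A = 0.40, B = 0.58, C = 0.57),
                          intervals = defaultIntervals(),
                          focalCountry = "Finland",
                          cityWeights = defaultCityWeights(),
                          pMultiCity = 0.25,
                          nUnlocatable = 0,
                          plantedEnrichedCityGenes = character(0),
                          seed = 1L) {
  new("SyntheticSpec",
      nPubs = as.integer(nPubs), yearRange = as.integer(yearRange),
      countryWeights = countryWeights,
      pInternational = as.numeric(pInternational),
      nGenes = as.integer(nGenes), zipfExponent = as.numeric(zipfExponent),
      genesPerPub = as.numeric(genesPerPub),
      geneticsFractionByInterval = geneticsFractionByInterval,
      intervals = intervals, focalCountry = focalCountry,
      cityWeights = cityWeights, pMultiCity = as.numeric(pMultiCity),
      nUnlocatable = as.integer(nUnlocatable),
      plantedEnrichedCityGenes = as.character(plantedEnrichedCityGenes),
      seed = as.integer(seed))
}

geneVocabulary <- function(nGenes)
  sprintf("G%04d", seq_len(nGenes))

intervalOfYear <- function(year, intervals) {
  for (nm in names(intervals)) {
    rg <- intervals[[nm]]
    if (!anyNA(rg) && year >= rg[1] && year <= rg[2]) return(nm)
  }
  NA_character_
}

# One country draw, then with probability pInternational a second distinct
# country, then further countries with a geometric tail (continuation
# probability 0.25 each).
drawCountries <- function(spec) {
  w <- spec@countryWeights
  ctry <- sample(names(w), 1, prob = w)
  if (stats::runif(1) < spec@pInternational) {
    pool <- w[setdiff(names(w), ctry)]
    ctry <- c(ctry, sample(names(pool), 1, prob = pool))
    while (stats::runif(1) < 0.25 && length(ctry) < length(w)) {
      pool <- w[setdiff(names(w), ctry)]
      ctry <- c(ctry, sample(names(pool), 1, prob = pool))
    }
  }
  ctry
}

synthAffiliation <- function(idx, city, country)
  sprintf("Institute of Biomedical Research %d, %s, %s", idx, city, country)

#' Generate a synthetic corpus with planted ground truth
#'
#' Draws \code{nPubs} publication records according to the specification
#' (see \code{\link{syntheticSpec}}). Each stage (years, genetics status,
#' genes, countries, cities, unlocatable replacement, enrichment planting)
#' consumes its own seeded random stream derived from the master seed, so
#' adding a stage never perturbs the draws of earlier stages.
#'
#' @param spec a \code{\link{SyntheticSpec}}.
#' @return List with elements \code{corpus} (a \code{\link{Corpus}}) and
#'   \code{truth}, a list recording the planted structure: per-interval
#'   genetics fractions, the gene vocabulary in true popularity order with
#'   its Zipf weights, the country weights, the per-record countries and
#'   cities as drawn, the ids of unlocatable records, and any planted
#'   enriched genes.
#' @export
generateCorpus <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  n <- spec@nPubs
  vocab <- geneVocabulary(spec@nGenes)
  zipfW <- seq_len(spec@nGenes)^(-spec@zipfExponent)
  zipfW <- zipfW / sum(zipfW)

  years <- withSeed(deriveSeed(spec@seed, 1), {
    sample(seq(spec@yearRange[1], spec@yearRange[2]), n, replace = TRUE)
  })
  intv <- vapply(years, intervalOfYear, character(1), spec@intervals)
  isGen <- withSeed(deriveSeed(spec@seed, 2), {
    p <- spec@geneticsFractionByInterval[intv]
    p[is.na(p)] <- 0
    stats::runif(n) < p
  })
  genes <- withSeed(deriveSeed(spec@seed, 3), {
    lapply(seq_len(n), function(i) {
      if (!isGen[i]) return(character(0))
      k <- min(1L + stats::rpois(1, spec@genesPerPub - 1), spec@nGenes)
      sample(vocab, k, prob = zipfW)
    })
  })
  countries <- withSeed(deriveSeed(spec@seed, 4), {
    lapply(seq_len(n), function(i) drawCountries(spec))
  })
  cities <- withSeed(deriveSeed(spec@seed, 5), {
    lapply(seq_len(n), function(i) {
      if (!(spec@focalCountry %in% countries[[i]]) ||
          !length(spec@cityWeights)) return(character(0))
      ct <- sample(names(spec@cityWeights), 1, prob = spec@cityWeights)
      if (stats::runif(1) < spec@pMultiCity && length(spec@cityWeights) > 1) {
        pool <- spec@cityWeights[setdiff(names(spec@cityWeights), ct)]
        ct <- c(ct, sample(names(pool), 1, prob = pool))
      }
      ct
    })
  })
  unlocIdx <- withSeed(deriveSeed(spec@seed, 6), {
    if (spec@nUnlocatable > 0) sort(sample.int(n, spec@nUnlocatable))
    else integer(0)
  })
  withSeed(deriveSeed(spec@seed, 7), {
    if (length(spec@plantedEnrichedCityGenes)) {
      target <- which(lengths(cities) > 0 & isGen)
      for (g in spec@plantedEnrichedCityGenes) {
        pick <- target[stats::runif(length(target)) < 0.5]
        for (i in pick) genes[[i]] <- unique(c(genes[[i]], g))
      }
    }
    NULL
  })

  affiliations <- lapply(seq_len(n), function(i) {
    if (i %in% unlocIdx)
      return(sprintf("Central Research Institute %d", i))
    ctry <- countries[[i]]
    affs <- character(0)
    for (c0 in ctry) {
      if (c0 == spec@focalCountry && length(cities[[i]])) {
        affs <- c(affs, vapply(cities[[i]], function(ct)
          synthAffiliation(i, ct, c0), character(1)))
      } else {
        affs <- c(affs, synthAffiliation(i, "Central City", c0))
      }
    }
    unname(affs)
  })

  corpus <- Corpus(
    pub_id = sprintf("S%06d", seq_len(n)), year = years,
    affiliations = affiliations, genes = genes,
    provenance = list(newProvenanceStep(
      "synthetic_generation", 0L,
      sprintf("generated %d records with seed %d", n, spec@seed))))
  truth <- list(
    geneticsFractions = spec@geneticsFractionByInterval,
    intervals = spec@intervals,
    geneRanks = vocab, zipfWeights = zipfW,
    countryWeights = spec@countryWeights,
    countries = countries,
    cities = cities,
    isGenetics = isGen,
    unlocatableIds = sprintf("S%06d", unlocIdx),
    plantedEnrichedGenes = spec@plantedEnrichedCityGenes)
  list(corpus = corpus, truth = truth)
}

#' Plant an exact joint-publication count for a gene pair
#'
#' Rewrites the corpus so that exactly \code{nJoint} records mention both
#' genes: the pair is first removed from any record that already carries
#' both, then both symbols are inserted into \code{nJoint} randomly chosen
#' genetics records. Used to create known edge/no-edge cases around the
#' co-occurrence threshold.
#'
#' @param corpus a \code{\link{Corpus}}.
#' @param geneA,geneB gene symbols.
#' @param nJoint exact number of records that must mention both genes.
#' @param seed RNG seed for the record choice.
#' @return The modified \code{\link{Corpus}}.
#' @export
plantGenePair <- function(corpus, geneA, geneB, nJoint, seed = 1L) {
  nJoint <- assertCount(nJoint, "nJoint")
  rec <- records(corpus)
  sets <- lapply(rec$genes, unique)
  both <- vapply(sets, function(g) all(c(geneA, geneB) %in% g), logical(1))
  # break existing co-mentions so the planted count is exact
  rec$genes[both] <- lapply(rec$genes[both], function(g) g[g != geneB])
  isGen <- lengths(lapply(rec$genes, unique)) > 0
  if (sum(isGen) < nJoint)
    stop(sprintf("only %d genetics records available for %d joint insertions",
                 sum(isGen), nJoint), call. = FALSE)
  pick <- withSeed(seed, sample(which(isGen), nJoint))
  rec$genes[pick] <- lapply(rec$genes[pick],
                            function(g) unique(c(g, geneA, geneB)))
  new("Corpus", records = rec,
      provenance = c(provenance(corpus), list(newProvenanceStep(
        "plant_gene_pair", 0L,
        sprintf("planted %d joint records for %s/%s", nJoint, geneA, geneB)))))
}
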