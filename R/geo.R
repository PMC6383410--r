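# Affiliation-to-place resolution: gazetteer, country extraction with
# last-token priority and right-to-left fallback, city extraction for a
# focal country, and removal of unlocatable records.

# Normalize a token for gazetteer lookup: drop e-mail fragments and digits,
# delete periods (so "U.S.A." -> "USA"), map other punctuation to spaces,
# lowercase and squeeze whitespace.
normalizePlaceToken <- function(x) {
  x <- gsub("\\S+@\\S+", " ", x)
  x <- gsub("\\.", "", x)
  x <- gsub("[0-9]", " ", x)
  x <- gsub("[[:punct:]]", " ", x)
  x <- tolower(x)
  trimws(gsub("[[:space:]]+", " ", x))
}

#' Read a gazetteer from TSV
#'
#' The file is UTF-8 TSV with columns \code{name}, \code{type} and
#' \code{canonical}. \code{type} is one of \code{country} (canonical country
#' name; \code{canonical} may repeat \code{name}), \code{alias} (e.g.
#' \code{UK -> United Kingdom}), \code{us_state} (state names and
#' abbreviations, all mapping to \code{United States}) and \code{city}
#' (focal-country city names). Keys are matched case- and
#' punctuation-insensitively.
#'
#' @param path TSV file; defaults to the gazetteer shipped with the package
#'   (world countries, common aliases, US states, Finnish cities).
#' @return A \code{\link{Gazetteer}}.
#' @export
readGazetteer <- function(path = NULL) {
  src <- if (is.null(path)) "packaged gazetteer" else path
  if (is.null(path))
    path <- system.file("extdata", "gazetteer.tsv", package = "litscape",
                        mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           encoding = "UTF-8", quote = "")
  stopifnot(all(c("name", "type", "canonical") %in% names(tab)))
  countries <- tab$canonical[tab$type == "country"]
  badAlias <- tab$type %in% c("alias", "us_state") &
    !(tab$canonical %in% countries)
  if (any(badAlias))
    stop("alias targets missing from country list: ",
         paste(unique(tab$canonical[badAlias]), collapse = ", "), call. = FALSE)
  isPlace <- tab$type %in% c("country", "alias", "us_state")
  lookup <- stats::setNames(tab$canonical[isPlace],
                            normalizePlaceToken(tab$name[isPlace]))
  lookup <- lookup[!duplicated(names(lookup))]
  isCity <- tab$type == "city"
  cities <- stats::setNames(tab$canonical[isCity],
                            normalizePlaceToken(tab$name[isCity]))
  new("Gazetteer", lookup = lookup, cities = cities, source = src)
}

#' @rdname readGazetteer
#' @export
defaultGazetteer <- function() readGazetteer(NULL)

lookupCountry <- function(token, gazetteer) {
  key <- normalizePlaceToken(token)
  if (!nzchar(key)) return(NA_character_)
  hit <- gazetteer@lookup[key]
  if (is.na(hit)) NA_character_ else unname(hit)
}

# Resolve one affiliation subgroup (text between ";" separators): split on
# ",", try the last comma-token first, then fall back right-to-left.
resolveSubgroup <- function(subgroup, gazetteer) {
  tokens <- strsplit(subgroup, ",", fixed = TRUE)[[1]]
  for (tok in rev(tokens)) {
    hit <- lookupCountry(tok, gazetteer)
    if (!is.na(hit)) return(hit)
  }
  NA_character_
}

#' Extract countries from raw affiliation strings
#'
#' Implements last-part text matching against a gazetteer: each affiliation
#' string is split into subgroups on \code{";"}, each subgroup into tokens
#' on \code{","}, and the last token (cleaned of whitespace, periods,
#' digits/postal codes and e-mail fragments) is matched against country
#' names, aliases and US states (which resolve to \code{"United States"},
#' covering affiliations that end in a state such as \code{"NY"}). If the
#' last token does not match, earlier tokens are tried right-to-left. The
#' result is the union over all subgroups of all affiliation strings;
#' an institution-only affiliation with no recognizable place yields no
#' countries (an empty vector, the "NA" outcome).
#'
#' @param affiliations character vector of raw affiliation strings.
#' @param gazetteer a \code{\link{Gazetteer}}.
#' @return Sorted character vector of canonical country names (possibly
#'   empty).
#' @examples
#' gz <- defaultGazetteer()
#' extractCountries("Tampere University, Tampere, Finland", gz)
#' extractCountries("Dept. of Urology, New York, NY", gz)   # United States
#' extractCountries("John Hopkins University", gz)          # character(0)
#' @export
extractCountries <- function(affiliations, gazetteer) {
  found <- character(0)
  for (aff in affiliations) {
    for (sub in strsplit(aff, ";", fixed = TRUE)[[1]]) {
      hit <- resolveSubgroup(sub, gazetteer)
      if (!is.na(hit)) found <- c(found, hit)
    }
  }
  sort(unique(found))
}

#' Extract focal-country cities from affiliations
#'
#' Scans the affiliation subgroups that resolve to the focal country and
#' matches gazetteer city names against their comma-tokens; a city name
#' embedded in an institution name (e.g. "University of Helsinki") also
#' matches, on word boundaries. Returns the union over all affiliations.
#'
#' @param affiliations character vector of raw affiliation strings.
#' @param gazetteer a \code{\link{Gazetteer}} carrying city entries.
#' @param focalCountry canonical country name the cities belong to.
#' @return Sorted character vector of canonical city names (possibly empty).
#' @export
extractCities <- function(affiliations, gazetteer, focalCountry) {
  if (!length(gazetteer@cities)) return(character(0))
  found <- character(0)
  for (aff in affiliations) {
    for (sub in strsplit(aff, ";", fixed = TRUE)[[1]]) {
      ctry <- resolveSubgroup(sub, gazetteer)
      if (is.na(ctry) || ctry != focalCountry) next
      norm <- normalizePlaceToken(sub)
      for (i in seq_along(gazetteer@cities)) {
        key <- names(gazetteer@cities)[i]
        if (grepl(paste0("\\b", key, "\\b"), norm))
          found <- c(found, unname(gazetteer@cities[i]))
      }
    }
  }
  sort(unique(found))
}

#' Annotate a corpus with countries and focal-country cities
#'
#' Applies \code{\link{extractCountries}} (and, when \code{focalCountry} is
#' given, \code{\link{extractCities}}) to every record, filling the
#' \code{countries} and \code{cities} columns.
#'
#' @param corpus a \code{\link{Corpus}}.
#' @param gazetteer a \code{\link{Gazetteer}}; defaults to the packaged one.
#' @param focalCountry canonical country name for city extraction, or
#'   \code{NULL} to skip cities.
#' @return The annotated \code{\link{Corpus}}.
#' @export
annotateGeo <- function(corpus, gazetteer = defaultGazetteer(),
                        focalCountry = NULL) {
  rec <- records(corpus)
  rec$countries <- lapply(rec$affiliations, extractCountries, gazetteer)
  if (!is.null(focalCountry)) {
    rec$cities <- lapply(seq_len(nrow(rec)), function(i) {
      if (focalCountry %in% rec$countries[[i]])
        extractCities(rec$affiliations[[i]], gazetteer, focalCountry)
      else character(0)
    })
  }
  new("Corpus", records = rec,
      provenance = c(provenance(corpus),
                     list(newProvenanceStep("geo_annotation", 0L))))
}

#' Drop records whose location could not be identified
#'
#' Removes records whose extracted country set is empty and records the
#' removal count in the corpus provenance.
#'
#' @param corpus a \code{\link{Corpus}} after \code{\link{annotateGeo}}.
#' @return The filtered \code{\link{Corpus}}.
#' @export
dropUnlocated <- function(corpus) {
  rec <- records(corpus)
  keep <- lengths(rec$countries) > 0
  new("Corpus", records = rec[keep, , drop = FALSE],
      provenance = c(provenance(corpus),
                     list(newProvenanceStep(
                       "drop_unlocated", sum(!keep),
                       "records with no resolvable country removed"))))
}
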