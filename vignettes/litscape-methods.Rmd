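---
title: "Methods: literature-landscape networks, enrichment and trends"
author: "litscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: literature-landscape networks, enrichment and trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litscape)
```

## The analysis in one paragraph

litscape takes a corpus of publication records, each annotated with a
publication year, raw author affiliation strings and the gene symbols
mentioned in the abstract, and derives from it a set of bibliometric
summaries: which countries and cities contributed, how they collaborate,
which genes are studied together, whether the genes a city studies are the
globally "highly studied" ones, and how the share of genetics research
evolved over time. The canonical use case is a disease-specific literature
(the package was validated with a prostate-cancer-like synthetic corpus),
but nothing in the code is specific to one disease.

The unit of analysis is always the publication. A record's *gene set* is
its deduplicated list of mentioned symbols; a publication is classified as
**genetics research** exactly when that set is non-empty. All counting
operations (gene counts, co-occurrence, gene-by-city counts) are
publication-based: a gene mentioned five times in one abstract counts
once. Raw mention counting is available via
`genePublicationCounts(unit = "mentions")` but is not the default, because
every network and enrichment construction downstream is publication-based.

## Affiliation-to-place resolution

Countries are extracted from raw affiliation text by gazetteer matching
rather than by a geocoding service. Each affiliation string is split into
subgroups on `;`, each subgroup into tokens on `,`. The *last* token —
after stripping e-mail fragments, digits/postal codes, periods and other
punctuation, case-insensitively — is matched against a table of country
names, common aliases (`UK`, `USA`, `Republic of Korea`, ...) and US state
names and abbreviations, which resolve to `United States` (affiliations
frequently end in a bare state such as `NY`). If the last token fails,
earlier tokens are tried right-to-left; this fallback keeps the last-token
priority while preventing trailing e-mails or postal codes from inflating
the unresolvable fraction. A record whose affiliations yield no match has
an empty country set and is removed by `dropUnlocated()`, which writes the
removal count into the corpus provenance — mirroring how such pipelines
report their dropped-abstract accounting.

Within one *focal country* (default `Finland`), cities are extracted from
the subgroups that resolved to that country. City names match on word
boundaries anywhere in the subgroup, so an institution name like
"University of Helsinki" locates the record even when the city is not a
separate token. This is deliberately more liberal than the country rule:
city lists are short, curated and unambiguous within one country, whereas
country matching must survive arbitrary world-wide text.

Known limitations: a US affiliation ending in "Georgia" resolves to the
country Georgia (the state is only recognized through its abbreviation
`GA`), and no province lists exist for countries other than the US. The
packaged gazetteer is a versioned plain-text TSV; users can supply their
own via `readGazetteer()`.

## Collaboration matrices

`countryMatrix()` and `cityMatrix()` build symmetric co-occurrence
matrices over per-publication entity sets: every unordered pair of
entities on a paper counts one collaboration (a paper with three cities
contributes three pairs), with no weighting by author multiplicity. The
diagonal stores **self-collaborations** — publications whose entity set is
a singleton. Per-entity publication totals are *not* row sums of this
matrix (a three-country paper appears in two pairs of each involved
country's row); they are kept as a separate vector, accessible with
`entityTotals()`. This separation resolves an ambiguity in the common
"row sums give publication totals" description, which only holds when no
paper has more than two entities; the self-collaboration definition is
the one actually used in reported statistics, so it owns the diagonal.

`groupOthers()` merges entities below a publication-total threshold
(default 1,000, the conventional cut for long-tail countries) into an
`Others` category. The merged diagonal absorbs both the members'
diagonals and their within-group pair counts, so the total over unordered
pairs including the diagonal is conserved. `chordExport()` emits the
positive pairs among the top-k entities as a `source,target,value` table
ready for chord-diagram tools. `selfCollaborationPct()` returns
`100 * |set == {country}| / |set contains country|` at full precision;
rounding happens only at report time (half-up, to the printed number of
decimals).

## Gene–gene literature networks

`geneMatrix()` builds the joint-publication count matrix *A* over gene
sets; its diagonal holds per-gene publication counts and is excluded from
thresholding. `thresholdGraph()` applies the strict rule
*B(i,j) = 1 iff A(i,j) > Θ* with Θ = 10 by default: an edge requires
*more than* 10 joint publications, so a pair with exactly 10 is cut. The
supporting statistic `pairExceedanceProbability()` reports the fraction
of *realized* pairs (≥ 1 joint publication) whose count exceeds Θ — the
quantity used to argue a threshold is conservative. The realized-pair
denominator was a design choice: an empirical frequency distribution of
jointly studied genes is only observable on pairs that co-occur at all;
with all C(G, 2) possible pairs as denominator the probability would be
even smaller, so the choice is conservative in the direction that
matters.

Communities default to the **connected components** of the thresholded
graph, isolated genes excluded, sorted by decreasing size. Components are
deterministic, reproduce the typical structure of such networks (a
dominant module bridged by one hub gene, plus small isolated pairs), and
need no tuning; a greedy-modularity alternative is available via
`graphCommunities(method = "modularity")` but is not the default because
the component structure is what the descriptive results rely on.

## Exact enrichment of highly-studied genes in a city

Every gene studied worldwide gets two binary attributes: **HS** (highly
studied), yes iff its worldwide publication count is strictly above a
threshold γ, and **City**, in iff the gene occurs in at least one
publication of the focal city. The 2×2 table of these attributes has
cells x (HS-yes, City-in), n12, n21, n22, with margins n+1 = x + n21
(city genes), n1+ = x + n12 (HS genes) and total n. Under the null that
highly studied genes are not preferentially the city's genes, x follows
the hypergeometric distribution

P(k) = C(n+1, k) · C(n − n+1, n1+ − k) / C(n, n1+),

and the reported p-value is the **strict tail** Σ P(k) for k = x+1 … n1+.
Note the observed x is *excluded*: this follows the definition used in
the source analysis literally, and is slightly anti-conservative compared
to the conventional one-sided exact test, which includes the observed
table (`includeObserved = TRUE` provides that variant). The sum is
computed in log-space via `lchoose`, so gene universes of several
thousand genes are handled without overflow. Any degenerate table (a zero
margin: no HS-yes gene, every gene HS-yes, or no city gene) returns p = 1
by convention — this is exactly what happens at the two extreme sweep
thresholds, where "nothing is selected" or "everything is selected" and
nothing can be enriched.

`enrichmentSweep()` repeats the test over a user-supplied γ list and
declares significance at α / m, m the number of thresholds (Bonferroni).
The γ list is taken verbatim from the user — published sweeps of this
kind are sometimes ambiguous about their exact threshold count, so the
package never hard-codes one.

Correctness is established two independent ways in the test suite: a full
subset-enumeration oracle over every margin combination with n ≤ 12
(agreement to 1e-12, including the strict-exclusion convention), and
`stats::phyper` as a second, library-independent route.

## Trend regressions

For each country (and for all countries pooled) `buildSeries()` computes
the yearly *percentage of genetics research*, 100 · genetics/total, over
the years the entity published; empty years are omitted, not imputed as
0%. Years are grouped into three intervals, A: 1987–1996, B: 1997–2006,
C: 2007–2018. `intervalRegression()` fits OLS of the yearly percentages
on a 0/1 interval indicator for a pair of adjacent intervals, so the
slope β1 *is* the difference of interval means (an identity the tests
verify to 1e-10) and its two-sided t-test is the reported hypothesis
test. The indicator coding — rather than regressing on calendar year —
was chosen because published slopes of 16–29 percentage points for such
analyses are implausible as per-year changes but natural as
between-interval jumps. Each year is one unweighted point; no weighting
by publication volume is applied. Family-wise control across the
per-country tests uses `bonferroniSignificant()` (p < α/m).

## The synthetic corpus generator

`generateCorpus()` emulates the structural features of a large annotated
biomedical corpus so every stage can be validated without any download:

* **Gene popularity** is Zipf: gene at popularity rank r is drawn with
  probability ∝ r^−s, s = 1.5 by default over a 500-gene vocabulary. A
  genetics abstract carries 1 + Poisson(1.5) genes (mean 2.5) — per-paper
  gene multiplicity is rarely reported, and a small shifted Poisson
  matches the intuition that most abstracts name a handful of genes.
* **Countries** follow a dominant-country distribution (40% United
  States) with a long tail of 19 further countries; with probability 0.15
  a paper is international (a second distinct country, further countries
  with a geometric tail of rate 0.25). The focal country Finland carries
  6% weight so that focal-city analyses have material sample sizes at
  moderate corpus sizes.
* **Genetics share by interval** defaults to A: 0.40, B: 0.58, C: 0.57 —
  a rise of about 18 percentage points between the first two intervals
  and a level continuation afterwards, the pattern reported for this
  literature.
* **Cities** within Finland are drawn with weights proportional to the
  seven cities' observed publication volumes (Helsinki 180 : Tampere 165
  : Turku 116 : Oulu 64 : Kuopio 58 : Espoo 12 : Jyväskylä 1); 25% of
  focal papers span two cities so that the city collaboration network is
  non-trivial.
* **Affiliations** are synthesized as `"Institute …, City, Country"`, so
  geo extraction runs on realistic-shaped strings; `nUnlocatable` records
  instead get institution-only strings that no gazetteer resolves,
  providing planted drop counts.

Each stage consumes its own seeded stream derived from the master seed,
so adding a stage never perturbs earlier draws, and the same spec + seed
is byte-reproducible. `plantGenePair()` rewrites a corpus so that a gene
pair co-occurs in *exactly* n records, giving sharp edge/no-edge cases at
the Θ boundary. What the generator does **not** emulate: real
affiliation dialects (department lists, missing commas, transliteration),
gene-symbol ambiguity and NER errors, within-interval growth trends, and
correlated country-gene preferences. Tests passing on synthetic corpora
therefore validate the *computations*, not the upstream annotation
quality of any real corpus.

## City clustering

`geneCityMatrix()` counts publications per (top-k gene, city) pair — the
default k = 19 matches the usual "top genes" cut reported for such
analyses — and `wardCluster()` clusters the *city* column vectors with
Ward's minimum-variance linkage on Euclidean distances
(`stats::hclust(method = "ward.D2")`, the Lance–Williams update that is
correct for Euclidean input). Raw counts are clustered without
standardization: the volume differences between cities are part of the
signal, and the source analyses state raw counts. `geneCityProportions()`
row-normalizes the same matrix (rows sum to 1 within 1e-12), exposing
"exclusively studied in city X" genes as rows with a single non-zero
entry. The number of clusters is read off the dendrogram by the analyst;
the package does not choose it.

## Validation design and problem sizes

The acceptance-grade checks are simulation-based, with all conditions
fixed a priori by power analysis:

* **Enrichment**: one 3,000-publication synthetic world (~260 observed
  genes); 200 replicates each of a *null* city (100 genes drawn
  uniformly — the hypergeometric null holds exactly) and a *planted* city
  (100 genes drawn with probability ∝ worldwide count, i.e. preferential
  attention to top genes); sweep over γ ∈ {0, 1, 2, 5, 10, 25, max}.
  Design-phase operating characteristics: family-wise false-positive
  rate ≈ 0.035 under the null (Bonferroni bound 0.05), all-interior-γ
  detection ≈ 1.0 under planting.
* **Trends**: the planted effect is a +18-point step between intervals A
  and B (0.40 → 0.58), measured on yearly percentages from binomial
  sampling at 25 publications/year × 10 years per interval. The per-year
  volume was set by a power analysis: at 10 publications/year the slope
  test has ≈ 0.69 power for an 18-point step (the yearly percentage SD
  is ≈ 15 points), which no 90%-recovery check can meet; 25/year gives
  ≈ 0.975 power, making the 200-replicate check stable. Null calibration
  uses 1,000 flat-null replicates (rejection ≈ α within two binomial
  standard errors).
* **Oracles**: exact-test enumeration runs over every margin set with
  n ≤ 12; brute-force matrix enumeration over 100-record corpora; Zipf
  rank recovery is measured on a 20,000-publication corpus, where tail
  genes are observed often enough that rank ties do not mask the planted
  ordering (Spearman ≈ 0.94).

These sizes keep the full test suite under a minute of simulation time
while leaving comfortable statistical margins.

## Numerical conventions

* Percentages are exact ratios internally; half-up rounding to the
  printed precision happens only in reports.
* The hypergeometric pmf is evaluated via log-gamma (`lchoose`);
  impossible terms contribute exactly 0 (`-Inf` in log space).
* Ties in top-k selections (genes, chord entities) break
  lexicographically by label, making every ranking deterministic.
* Thresholds Θ and γ are strict (`>`) everywhere, matching the network
  rule B(i,j) = 1 iff A(i,j) > Θ; boundary counts equal to the threshold
  are excluded.
* All randomness flows from explicit seeds; generator and pipeline calls
  restore the caller's RNG state.

## A worked micro-example

```{r example}
sim <- generateCorpus(syntheticSpec(nPubs = 800, seed = 42))
corpus <- dropUnlocated(annotateGeo(sim$corpus, focalCountry = "Finland"))
corpus

head(genePublicationCounts(corpus), 5)

gm <- geneMatrix(corpus)
tg <- thresholdGraph(gm, theta = 10)
tg

w <- genePublicationCounts(corpus)
cityGenes <- unique(unlist(records(corpus)$genes[
  vapply(records(corpus)$cities, function(s) "Helsinki" %in% s, logical(1))]))
enrichmentSweep(w, intersect(cityGenes, names(w)),
                gammas = c(0, 2, 5, 10, 25, max(w)))
```
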