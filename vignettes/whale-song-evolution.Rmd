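---
title: "Quantifying humpback whale song evolution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying humpback whale song evolution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whalesong)
```

Male humpback whales (*Megaptera novaeangliae*) sing a hierarchically
structured display: discrete **units** combine into **phrases**, repeated
phrases form **themes**, and an ordered pass through the themes is a **song
cycle**. Because song is learned socially and conforms strongly within a
population while changing progressively between seasons ("song evolution"),
symbolic transcriptions of song are a sensitive assay of cultural
transmission and of acoustic contact between populations. `whalesong`
implements the quantitative half of such an analysis: sequence-similarity
indices over transcribed phrase-type sequences, hierarchical clustering
with support and fit diagnostics, a PCA-based song-complexity score with a
year-effect model, and first-order theme-transition summaries — together
with a seeded synthetic-corpus generator for validating the whole pipeline.

This vignette records the model choices, parameter conventions and known
limitations. It states no empirical result beyond what the package's test
suite and `scripts/acceptance.R` themselves compute.

## The corpus model

A `song_corpus` holds `singer_recording`s (singer, year, site, date,
length, optional SNR), each with one or more `song_cycle`s. A cycle's
phrase sequence uses **phrase-type labels**: a theme number, an optional
variant letter `a`–`d`, and zero to two trailing `e` marks flagging an
evolved (between-year changed) version — `"2"`, `"5c"`, `"5ce"`, `"1ee"`.
Variant-less labels are legal; the grammar round-trips losslessly through
`parse_label()` / `format_label()`. Transcriptions remove immediate phrase
repetition but keep consecutive alternation of one theme's phrase types
(the "variable theme" pattern), so collapsing a cycle to themes
(`collapse_to_themes()`) merges consecutive duplicates only.

Two eligibility rules are implemented in `filter_recordings()`: a unit
signal-to-noise threshold (default: keep recordings above 10 dB) and a
minimum separation between same-site, same-year recordings (default 24 h;
the earlier recording is kept) to reduce the chance of re-sampling one
singer. Recordings without an SNR value fail the SNR rule while it is
enabled; the packaged corpus was screened upstream, carries no SNR values,
and therefore ships pre-filtered. Phrase segmentation from unit streams
(`segment_phrases()`) uses the largest-gap principle with a scale-free
boundary: a new phrase starts where an inter-unit gap exceeds `k` times
the median gap (default `k = 3`), which transfers across singers with
different tempi without an absolute threshold.

The packaged Okinawa 2011–2013 corpus (17 singers, two sites) is shipped
as a plain transcription table. Printed-table whitespace artefacts
(`"8 a"`, `"9 a"`, `"5 d"`) are normalised on ingestion. One label is
genuinely ambiguous: singer 3's bare `"3 "`. We keep it as the
variant-less phrase type `"3"` — consistent with the accepted variant-less
`"2"` and `"6"` — and expose `okinawa_song_corpus(three_as = "3a")` for
the alternative reading. Singer 12 lacks a complete cycle and is flagged
`complete = FALSE`; similarity and complexity analyses exclude it, while
transition tabulations keep it.

## Sequence similarity

`levenshtein_distance()` is the unit-cost edit distance over whole tokens:
`"5c"` and `"5ce"` are different tokens at distance one, which is exactly
how an evolved phrase should count — changed material, not partial credit.
The **Levenshtein similarity index** is
`LSI(a, b) = 1 − d(a, b) / max(|a|, |b|)`, in `[0, 1]`.

Per singer we compare one representative sequence: the **set median** of
the singer's cycles (the member minimising the summed edit distance to the
others). The set median is restricted to members of the set; a generalised
median string is deliberately not offered. With two transcribed cycles the
sum ties by symmetry, so the tie rule matters: the default keeps the
earliest cycle (`ties = "first"`), and `ties = "last"` is available for
sensitivity analysis. Median sequences stay at phrase-type resolution by
default (`tokenization = "phrase_type"`) because the evolved-`e` marks are
precisely what separates adjacent years; collapsing to bare themes erases
them, and the year structure of the dendrogram degrades accordingly (this
is observable with `tokenization = "theme"`).

**Dice's similarity index** ignores order entirely:
`DSI(A, B) = 2|A ∩ B| / (|A| + |B|)` over per-singer phrase-type
inventories (presence/absence; multiplicity ignored). A theme-level switch
(`dice_matrix(level = "theme")`) is provided; phrase-type level is the
default for the same reason as above.

## Clustering, cophenetic fit, and bootstrap support

`upgma()` implements unweighted pair-group average linkage with node
height equal to the average inter-cluster distance at the merge, returning
a standard `hclust` object. Ties are broken by the lexicographically
smallest pair of cluster labels, so results are independent of input
order — important because bootstrap resampling re-clusters thousands of
perturbed matrices.

Two similarity-to-distance conventions are exposed by `to_distance()` and
`cluster_similarity()`:

* `"complement"`: `d = 1 − s`, the direct reading of a similarity matrix;
* `"profile_correlation"`: `d = 1 − cor` between the objects' similarity
  profiles (the matrix's columns). This is what a similarity matrix
  receives when it is handed to multiscale-bootstrap clustering software
  as a data matrix, and it is the convention under which the pipeline
  reproduces the published cophenetic correlations for this corpus; it is
  therefore the default in `cluster_similarity()` and
  `okinawa_reproduction()`. The complement convention remains available
  for sensitivity analysis.

The **cophenetic correlation coefficient** (`ccc()`) — the Pearson
correlation between input distances and tree-implied cophenetic
distances — summarises how faithfully the dendrogram represents the
matrix; values above 0.8 are conventionally a good fit, and the
coefficient is exactly 1 on ultrametric input.

`bootstrap_support()` attaches **BP** and **AU** probabilities to every
clade. The resampling unit is a feature row of a profile matrix; for
sequence-derived similarity matrices the natural profile is the similarity
matrix itself, each object's row of similarities acting as its feature
vector (`dist_method = "correlation"`). For each scale
`r ∈ {0.5, 0.6, …, 1.4}` (defaults), `⌈r·n⌉` rows are resampled with
replacement `B = 1000` times and the clade's appearance proportion
`BP(r)` recorded. The multiscale model
`qnorm(1 − BP(r)) = v·√r + c/√r` is fitted by weighted least squares with
binomial-variance weights (`fit_multiscale()`); `AU = 1 − Φ(v − c)`, and
BP is reported at `r = 1`. Proportions of exactly 0 or 1 receive a
continuity correction of `0.5/B`; a clade saturated at 0 or 1 across all
scales makes the signed-distance model degenerate, so its AU is capped at
the corresponding extreme rather than fitted; a clade with fewer than two
usable scales reports `NA` rather than a guess. The conventional reading
is AU > 95 (significant) and BP > 70 (strong). Because the original
choice of resampling profile for a precomputed similarity matrix is not
uniquely determined, AU/BP values should be interpreted as significance
thresholds, not exact reproducible statistics. Dendrograms export to
Newick (`to_newick()`) with halved ultrametric branch lengths and
`"au/bp"` node labels.

## Song complexity

Four per-song variables feed the complexity score: number of units,
number of distinct unit types, duration (last unit offset minus first
onset, seconds) and number of distinct themes. Counts and duration are
natural-log transformed; the left-skewed theme count is squared
(`transform_complexity()`); the log base is immaterial because variables
are standardised before the PCA. Shapiro–Wilk and Pearson reports
(`normality_report()`, `correlation_report()`) are diagnostics, not gates.

`complexity_scores()` runs the PCA on the correlation matrix by default
and extracts the first component score per song. The original analysis
used a PCA routine whose default operates on the covariance matrix, and
its printed near-equal loadings are consistent with standardised input;
since the per-song variable table needed to settle this was not released,
the scale is a documented switch (`standardize = FALSE` for the
covariance option), not a claim. The component sign is oriented so the
loading on log units is positive — more units means higher complexity.
Scores are averaged per singer (`average_by_singer()`) so singers with
more transcribed songs do not dominate. Variance homogeneity across years
is checked with Bartlett's test (`bartlett_by_year()`), and the year
effect is estimated by ordinary least squares with year indicator-coded
against the earliest year (`year_regression()`); this coding is the one
that reproduces both published year t statistics simultaneously from the
shipped per-singer scores, even though one of them is described in prose
as a year-over-year increase.

## Theme transitions and stereotypy

`transition_counts()` tabulates first-order theme-to-theme transitions
within collapsed cycles, per year. Cycle boundaries are hard breaks — no
wrap-around transition from a cycle's last theme — because cycles are
delimited precisely to avoid that ambiguity. Proportions are
row-normalised; transitions observed once carry a marker that renders as
a dotted edge in the DOT export. `stereotypy()` summarises a matrix as
the mean Shannon entropy (bits) of the outgoing distributions, weighted
by row counts: 0 bits is fully deterministic sequencing, and the maximum
is `log2(k − 1)` for `k` themes without self-transitions.

## The synthetic-corpus generator

`generate_corpus()` simulates the statistical structure the analysis
assumes, with a `TruthRecord` sufficient to recompute every expected
quantity. Its defaults describe a study-like corpus: 3 years × 5 singers
× 2 cycles, a 6-theme initial inventory with one variable theme whose two
phrase types alternate, about 250 units and 56 phrases per song and
~400 s songs at baseline (so a corpus is of the same order as the
~7500-unit, ~1700-phrase field corpus).

Year inventories evolve between years: each theme gains an `e` mark with
probability 0.5 (capped at two marks), is lost with probability 0.15, and
new themes arrive as a Poisson(1) innovation stream — roughly one
innovation, one loss and three evolutions per transition, matching the
qualitative turnover in the packaged corpus. At the unit level, an
evolved theme changes exactly one token class of its alphabet, the
granularity at which this pipeline observes phrase change.

Within a year, singers perturb the canonical theme order by adjacent
swaps (probability 0.1 per position) and omit themes. Omission follows a
per-year popularity ranking, so songs that omit themes all omit the same,
least popular ones: theme sets are nested, which preserves the
within-year conformity real corpora show (in the packaged corpus the
commonly omitted theme is the variable theme). With `dropout = 0` every
song carries the full inventory.

The four complexity variables follow an explicit one-factor model on the
transformed scale. Each song draws a common factor `f ~ N(0, 0.25²)` and
channel noise `e_i ~ N(0, 0.2²)`; log units, log unit types, log duration
and log squared theme count are each shifted by `f + e_i` plus the year's
log effect, and the song is then synthesised to realise those targets
exactly (counts by construction, duration by rescaling the unit
timeline). Standardised, the three continuous channels are equicorrelated
with `λ = σ_f²/(σ_f² + σ_e²)`, giving the classic `(1 + 3λ)/4` first
eigenvalue share in the continuous limit. The theme channel, however, is
an integer count clamped by the inventory, which attenuates its
correlation; `expected_pc1_fraction()` therefore computes the
model-implied PC1 share exactly — one-dimensional Gaussian quadrature for
the discretised theme channel, year effects entering as a mixture — and
this is the reference value the recovery checks compare against.

The default year effects (1, 0.7, 1.6) encode the
decrease-then-rebound complexity trajectory. They were chosen so the
realised standardised contrasts stay within the range the field corpus
itself exhibits while being unambiguous relative to the generator's own
sampling noise at 5 singers per year — a weaker configured rebound is
recovered with the wrong sign in a non-negligible share of corpora
simply because ten songs per year leave the year-mean factor draw that
uncertain, which would test luck rather than the pipeline.

`recovery_suite()` runs the full analysis over seeded corpora and
reports: year-cluster purity (cut the LSI tree into one cluster per year;
majority-year fraction), the sign-recovery rate of the configured year
effects, and the mean PC1 fraction against `expected_pc1_fraction()`. The
shipped checks use 20 corpora for purity and the PC1 share and 100 for
signs — sizes at which the Monte Carlo error of each summary is small
relative to its acceptance margin. Purity is checked under low sequence
noise (swap probability 0.02, dropout 0.05); in the degenerate limit with
maximal swap noise and a frozen inventory the years are statistically
identical and purity falls to chance, which the suite also asserts.

What the generator does **not** emulate: acoustic measurement and unit
classification error (transcriptions are taken as given), singer identity
across years, within-season drift, multi-population contact and song
revolutions, and realistic phrase-internal syntax beyond stereotyped
repetition. A pipeline that passes the recovery checks is validated
against this idealised structure, not against everything field data can
do.

## Numerical conventions and degenerate inputs

* Edit distance on two empty sequences is 0, but the LSI of two empty
  sequences is undefined (no normaliser) and errors.
* UPGMA rejects `NA` distances; agglomeration ties break
  lexicographically; heights are merge distances and are non-decreasing.
* In profile-correlation distances a zero-variance profile would make the
  correlation undefined; such entries are treated as correlation 0
  (distance 1).
* The CCC needs at least three leaves; Bartlett's test needs two values
  per group and positive within-group variance; the PCA needs five songs
  and at least one informative dimension; all error informatively below
  those floors.
* All generator randomness flows from the single integer seed in its
  configuration; the same configuration is byte-identical across runs.

## Reproducing the shipped analysis

`okinawa_reproduction()` runs the full pipeline on the packaged corpus
and returns the clustering objects, regression, Bartlett test, transition
matrices and stereotypy values in one list; `scripts/acceptance.R`
recomputes the same quantities from scratch and writes them as JSON. The
per-singer average complexity scores are shipped as published because the
per-song unit-level measurements behind them were not released; the
similarity, transition and synthetic-recovery results are computed
entirely from the transcription table and the generator.
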