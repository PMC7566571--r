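---
title: "isomiRscope: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{isomiRscope: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

isomiRscope analyses what happens when a mature miRNA is expressed as a
population of sequence variants (isomiRs) rather than a single annotated
species. A 5' isomiR shifts the seed (positions 2–8), and with it the
entire predicted target repertoire; the package follows that shift from
raw small-RNA reads through target prediction, ranked-list enrichment,
and a compendium-scale surrogate analysis that uses the host gene of an
intronic miRNA as a proxy for the miRNA's own expression change. Every
stage can be driven by the built-in synthetic generators, which emit
ground-truth manifests so the whole pipeline is testable without any
external download.

```{r setup, eval = FALSE}
library(isomiRscope)
```

## 1. IsomiR cataloguing

Reads are matched exactly (no mismatches) against the mature miRNA
embedded in its hairpin plus genomic flanks (default 10 nt per side).
For each read the aligner finds the longest 3' suffix that cannot be
explained by templated sequence — tail lengths 0, 1, 2, … are tried in
order and the first (longest templated core) placement anchored within
`max_shift` (default 5 nt) of the mature 5' end wins. Among equally long
cores the placement with the smallest absolute 5' offset is taken, ties
resolved toward the more negative offset; a read matching several
matures is assigned to the one with the smallest absolute 5' offset,
ties broken lexicographically by reference name, and flagged ambiguous.
Greedy templated extension is deliberately conservative: it minimises
nontemplated calls, so a reported tail is always a sequence the genome
cannot account for.

Conventions:

* `five_prime_offset = mature 5' start − read 5' start`, so a read
  starting one nucleotide downstream (shifted toward the 3' direction,
  hence a shifted seed) has offset −1.
* category: `canonical` (offsets 0/0, empty tail), `5prime_only`,
  `3prime_only` (3' offset and/or a nontemplated tail), `mixed`.
* `templated` is simply "empty nontemplated tail".

5' isomiR calls require all of: a 5' shift of at least 1 nt, a read
count strictly greater than 100, and a fraction of the miRNA's reads
strictly greater than 5%. Both thresholds are strict: a count of
exactly 100 or a fraction of exactly 0.05 never passes. The fraction
denominator is configurable (`fraction_denominator`): the default
`arm_total` divides by all reads assigned to the mature arm, which is
the more conservative choice; `canonical_only` divides by reads exactly
matching the annotation. Both readings circulate in practice and they
disagree only in degree, never in direction.

Seed groups collapse a miRNA's records by seed heptamer and are named
`.1`, `.2`, … in descending read count. Published suffixes are fixed
conventions rather than derivable facts, so `group_by_seed()` accepts an
override map to reproduce them.

## 2. Target sites

From a mature (or isomiR) sequence the four canonical site motifs are
derived in the mRNA sense: the 6mer is the reverse complement of miRNA
positions 2–7, the 7mer-m8 of positions 2–8, and the 7mer-A1/8mer append
a literal adenosine — the position-1 A is an mRNA feature recognised by
Argonaute, not a complement of the miRNA's first base. Scanning anchors
at every occurrence of the 6mer core (overlaps allowed) and promotes
each anchor to the strongest matching class (8mer > 7mer-m8 > 7mer-A1 >
6mer), so nested matches at one anchor are never double-counted. The
default stringency for calling a gene a predicted target is 7mer-A1.

A structural fact worth knowing when interpreting results for a −1
5' isomiR pair: the shifted species' 6mer core is always the first six
bases of the annotated species' 7mer-m8 site, so every strong site for
the annotated species contains a weak site for the shifted one. The
converse holds only when the mature's second base is U. Conservation
scoring (as used by database target lists) is out of scope; externally
produced lists can be imported with `read_target_list()` and used in
all downstream statistics.

## 3. Ranked enrichment

`rank_genes()` orders a DE table from most down- to most up-regulated
(ascending log2FC, ties broken lexicographically by gene id, so the
ranking is independent of input row order). For a site word of 6–8 nt,
`word_landscape()` computes at each leading-set cutoff *t* (every `step`
genes, default 100, plus the final cutoff *N*) a signed enrichment
value: with *K* of *N* genes carrying the word and *x* of them in the
leading *t*,

value = −log10 P(X ≥ x) if x/t ≥ K/N, else +log10 P(X ≤ x),
X ~ Hypergeometric(N, K, t).

Positive values mean enrichment among down-regulated genes. Counting is
by gene presence/absence of the word, not occurrence totals, and no
sequence-composition correction is applied; both choices are recorded
in the result metadata. Presence/absence makes the statistic exactly
checkable against brute-force enumeration (the test suite verifies all
instances with N ≤ 12); an occurrence-weighted mode with composition
correction is the main respect in which this implementation is simpler
than the classic word-enrichment landscape tools.

Directional statistics use the convention: significant means adjusted
P < 0.05 (configurable `alpha`), direction by the sign of log2FC, and a
significant gene with log2FC exactly 0 counts as no change. An empty
direction class yields a missing percentage, never zero. The
two-distribution comparison defaults to a two-sided Mann–Whitney U
test; the original analysis this emulates does not name its test, so
the choice is this package's own and a Welch t-test is selectable.

## 4. Host-gene surrogate analysis

For an intronic miRNA co-transcribed with its host gene, the host's
expression change across many studies serves as a surrogate for the
miRNA's change. The module filters a compendium to studies where the
host changes significantly (adjusted P < alpha, no fold-change cutoff),
then per study computes the mean predicted-target log2FC, the percentage
of targets among significantly up- and down-regulated genes, their
up/down enrichment ratio, and the same statistics for a random control
set (default 500 genes, drawn once per study with a study-derived seed
offset so results are reproducible and row-order invariant). Mean
target fold change is regressed on host fold change by OLS; r² is the
squared Pearson correlation and the slope P-value a two-sided t-test.

Decisions where the emulated analysis is silent: enrichment ratios are
undefined (missing, with counts reported) when the percent-down
denominator is missing or zero, rather than infinite; studies are
grouped host-down vs host-up by the sign of the host log2FC with exact
zeros assigned to neither; group contrasts default to a two-sided Welch
t-test; and per-study target means are taken over all genes present in
each study's table, with no additional expression filter.

## 5. The synthetic generators

The generators define the study conditions and emit exact truth:

* `gen_locus()` draws a hairpin (default 110 nt, 22 nt matures, 10 nt
  flanks) with one 5p and one 3p mature. Two constraints make truth
  exact and the system representative: the eight bases downstream of
  each mature 3' end are non-A, so a nontemplated adenine is never
  confusable with templated extension; and the second base of each
  mature is non-U, so the annotated and −1-shifted seed registers give
  distinct site motifs — the situation of interest, in which a seed
  shift rewires the target repertoire.
* `gen_read_pool()` draws multinomial counts over an isomiR mixture.
  The default composition emulates an abundantly modified 3p miRNA:
  ~5% exactly canonical reads, roughly half the reads in a −1-shifted
  seed register, heavy templated 3' extension, and a 0.3 probability of
  one extra nontemplated adenine — jointly giving about 25–30% fully
  templated reads and two seed groups covering all reads. A composition
  whose nontemplated tail begins with the next templated base is
  rejected outright, because no aligner could (or should) distinguish
  it.
* `gen_utrome()` plants site motifs at known positions in otherwise
  seed-free background (uniform A/C/G/U with rejection of accidental
  6mer cores; occurrences overlapping a planted span are allowed, since
  overlapping seeds necessarily share site sequence). Guard bases
  prevent accidental promotion, so the planted type is exactly the
  strongest type a scanner reports.
* `gen_de_table()` plants repression: targets at Normal(−delta, sd²),
  others at Normal(0, sd²), adjusted P from two-sided z-tests (known
  sd) with Benjamini–Hochberg correction — matching the adjusted-P
  convention of the consumed DE tables without modelling platform
  variance.
* `gen_compendium()` draws per-study host log2FC uniformly over ±2 and
  shifts a fixed target set by `coupling_beta × host + study noise`;
  per-gene noise (sd 0.3, a realistic within-study dispersion) is
  mean-centred within the target set, so the realized mean target shift
  is exactly the coupled value and a noiseless compendium recovers the
  planted slope to machine precision.

What the generators do **not** emulate: sequencing error, adapter
artefacts, expression-dependent detection, UTR isoform diversity (one
UTR per gene, not the longest-isoform choice a database would make),
conservation, correlated genes within studies, or cross-study
platform effects. Passing tests therefore demonstrate correctness of
the algorithms under clean conditions, not robustness to those
real-data complications.

## 6. Numerical choices and degenerate inputs

* All randomness flows through integer seeds (R's default generator);
  the pipeline derives per-stage seeds from one config seed by fixed
  offsets, and manifests record the seeds used.
* Landscape values are finite by construction (the enriched branch uses
  P(X ≥ x) which is ≥ P(X = x) > 0; the final cutoff is exactly 0).
* Empty classes, empty target intersections and undefined ratios
  propagate as missing values with counts reported — never silent
  zeros; genuinely contradictory inputs (duplicate genes, unknown set
  ids, degenerate regressor variance) are errors.
* Alignment rejects reads shorter than 16 nt or longer than 30 nt and
  routes unplaceable reads to a reject table rather than failing.
* The strict `>` in both 5' isomiR thresholds is load-bearing: a
  count-100 or fraction-0.05 record must not pass.

## 7. Problem sizes

The bundled analysis scripts and the default configuration use the
conditions the statistics are designed around: 10⁵ reads, 2000 genes
with 200 planted targets (repression 1 log2 unit, sd 0.5), 200 nt UTRs,
and a 124-study compendium (coupling −0.4, study noise 0.1, 5% targets,
500-gene random control). The test suite runs the same conditions with
20 replicate seeds for stochastic checks and 100 seeds for the
null-calibration check of the regression P-value (on smaller, 400-gene
study tables, which the calibration does not depend on); exhaustive
hypergeometric verification covers every instance with N ≤ 12.

## 8. Known limitations

Exact matching only (no mismatch tolerance — the templating logic
presumes it); no probabilistic resolution of multi-mapping reads; no
isomiR nomenclature standard beyond the abundance-ranked suffixes; no
conservation or context scoring of sites; no composition correction in
the landscape; the surrogate analysis assumes a pre-harmonised gene
namespace across studies.
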