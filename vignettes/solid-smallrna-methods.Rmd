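---
title: "Methods: color-space small RNA-seq analysis with mirsolid"
author: "mirsolid authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: color-space small RNA-seq analysis with mirsolid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsolid)
```

# Scope and model

mirsolid analyses small RNA deep-sequencing data produced in SOLiD
di-base *color space*, end to end: read parsing and adapter trimming,
mismatch-budgeted matching against a reference, hierarchical exclusive
annotation, miRNA quantification and normalization, empirical-Bayes
moderated-t differential expression, pre-miRNA arm profiling, an exact
color-space census for disambiguating near-identical mature miRNAs, and
canonical seed-site scanning with hypergeometric target enrichment. A
first-class synthetic-data generator reproduces the statistical structure
of an adipogenic differentiation study (baseline vs differentiated stem
cells) so that every stage can be validated against known truth without
external downloads.

## Color space

Each SOLiD color symbol 0–3 encodes the transition between two adjacent
bases. With the 2-bit codes A=0, C=1, G=2, T=3, the di-base matrix
(identical pair→0; A↔C=1; A↔G=2; A↔T=3; C↔G=3; C↔T=2; G↔T=1) is exactly
bitwise XOR, which gives three algebraic facts the package leans on and
property-tests:

* encoding is invertible given the anchoring primer base
  (`decode_colorspace(encode_colorspace(s, p)) == s`);
* a single base substitution changes exactly two adjacent colors
  internally and exactly one color at the 3' terminus — the basis of the
  twin/decoy disambiguation logic;
* colors are complement-invariant: the internal colors of the reverse
  complement are the reversed internal colors, so minus-strand matching
  and opposite-direction sequencing reduce to string reversal.

**Internal colors.** The first color of a read depends on the sequencing
primer (and, for an insert, on the adapter junction), not on the genome.
All matching, trimming and censusing therefore operate on the read's
*internal* colors — the color string with the primer-adjacent first color
dropped. The seed mismatch budget covers the first 18 internal colors.

## Adapter trimming

Inserts of 15–50 nt are sequenced as fixed 35-color reads, so short
inserts run through into the 3' adapter. The trimmer removes the longest
read suffix whose colors match the adapter's internal colors exactly,
skipping the insert/adapter junction color (which depends on the last
insert base); one color mismatch is tolerated when the overlap is at
least 10. Trimming in color space, not in decoded bases, is essential: a
single color error corrupts every decoded base downstream of it but
leaves all other colors intact. The adapter is tiled so that adapter
dimers trim to length zero and are flagged `too_short`. A consequence of
the fixed read length is that inserts longer than
`read length − min_overlap` can never be trimmed and usually fail to map;
the generator's insert templates stay below that bound.

## Matching and the mismatch budget

`match_reads()` reports every reference location, on both strands, where
the read's internal colors differ by at most 1 color in the first 18
("seed") and at most 2 on the following positions — the historical SOLiD
small-RNA mapping parameterization, all budgets configurable via
`match_params()`. Reads shorter than the seed use their full length as
the seed. Color mismatches are counted directly, with no SNP-aware
two-adjacent-color correction, matching how the original tooling counted
them. The implementation is seed-and-extend over a 7-mer color index with
a pigeonhole split of the seed region (`seed_mismatch_max + 1` exact
pieces); parameter settings outside the pigeonhole guarantee fall back to
a full scan. The test suite holds the implementation to *exact* agreement
with a literal brute-force scan of every offset and strand on dozens of
random genomes.

## Exclusive assignment hierarchy

Each mapped read is assigned to exactly one category. Among its best
(fewest total mismatches) hits, features overlapping a hit by at least
50% of the read length on the same strand compete; the winner is the
highest-priority class in the hierarchy

`miRNA_human > miRNA_other_species > transcript > piRNA > tRNA > rRNA >
snoRNA > other_ncRNA`,

with `non_annotated` for mapped reads claiming no feature and `unmapped`
otherwise. The order follows the annotation-class listing of the study
the package emulates and is configurable; the original pipeline's
database gating (genome, then miRNA catalogues, then other ncRNA) is
treated as this category priority rather than as separate mapping passes.
Ties within a class are broken by feature specificity — the smallest
feature wins, so a mature miRNA beats the precursor that spans it, and
isomiR end-variants still count toward the mature feature — then by
leftmost coordinate, for deterministic output. Multi-mapped reads count
once, toward the single tie-broken feature, because the downstream tables
report integer read counts.

## Quantification and normalization

Raw counts are reads per mature miRNA per sample; normalized counts scale
each sample's miRNA counts to a total of 10^6 ("counts per million miRNA
reads", cpm), so per-sample normalized columns sum to exactly 10^6 —
asserted, not approximated. Relative abundances are percentages of miRNA
reads; condition-level values average the per-sample percentages rather
than pooling counts, matching how the emulated study reported averages of
per-sample sequencing frequencies. Pre-miR profiles report per-base
coverage in precursor 5'→3' orientation plus 5p/3p arm counts under the
same 50%-overlap rule. `comparative_ct()` implements the qPCR 2^−ΔCT
companion calculation with reference-gene averaging.

## Differential expression

The model is a per-feature one-way Gaussian linear model on
`log2(cpm + 0.5)`. The pseudocount of 0.5 keeps condition-specific
miRNAs (zero baseline counts) finite while shifting abundant features
negligibly; the log transform makes a Gaussian model defensible for
count ratios. Technical replicates — the two opposite sequencing
directions of each library — are averaged on the log scale into one
value per biological replicate before fitting, to avoid
pseudo-replication.

Residual variances s² (d residual df) are shrunk toward a prior (d0,
s0²) estimated across features by matching the mean and variance of
log s² to the log chi-square (scaled-F) distribution via
digamma/trigamma moment equations, with the trigamma inverted by Newton
iteration. The moderated statistic for a contrast is

t = Δmean / sqrt(s̃² (1/n_a + 1/n_b)),  s̃² = (d0·s0² + d·s²)/(d0 + d),

with two-sided P on d0 + d df. When the spread of log variances does not
exceed chi-square sampling noise, d0 is infinite and every feature
shrinks to the mean variance — the defined degenerate behaviour. Features
with zero residual variance are excluded from prior estimation but still
shrunk. The implementation is the package's own; the test suite checks it
at 1e-10 against an independent closed-form evaluation and checks the
estimated prior against an established external implementation of the
same estimator.

Feature selection mirrors the emulated analysis: only miRNAs whose
condition-mean cpm reaches 300 (= 0.03% relative abundance) in at least
one condition are tested, and the regulated set is raw P < 0.05, with
Benjamini–Hochberg adjusted values always reported alongside for honesty
about multiplicity.

## Disambiguating near-identical miRNAs

Two annotated mature sequences differing at a single 3'-terminal base
differ at exactly one color. `perfect_match_census()` converts each
candidate to color space and counts raw reads whose internal colors carry
the candidate's internal colors exactly, at read offset 0 by default —
inserts start at the adapter junction, so offset 0 is where a mature
miRNA's colors must sit; an any-offset mode is provided for fragment
searches. Reads from the opposite sequencing direction are censused with
the reversed candidate colors. `positional_quality()` then reports the
quality values at the discriminating color positions against the
read-wide mean: a genuine rare species keeps high quality there, whereas
sequencing errors of an abundant twin do not. With a per-color error rate
e, a twin at abundance A feeds its decoy at roughly A·e/3 (the terminal
color must flip to one specific alternative with no other error), so a
14:1 planted pair stays far above a 5:1 census ratio at e = 1% — the
package's quantitative rendition of the argument that a low-count decoy
annotation can be explained by sequencing error.

## Target sites and enrichment

`find_seed_sites()` reports canonical 6mer / 7mer-A1 / 7mer-m8 / 8mer
sites: exact Watson–Crick complementarity of miRNA bases 2–7 (plus base 8
for m8 types) on the UTR sense strand, with the anchoring adenosine
opposite miRNA position 1 at the site's 3' end. G:U wobble is not
allowed, following the canonical site definitions. Conservation scoring
is out of scope; a user-supplied conservation flag can be carried as
metadata but is never computed. `enrichment_test()` is the upper
hypergeometric tail of the overlap between predicted-target and regulated
gene sets in a universe, with fold enrichment = observed/expected; the
tests verify it against exhaustive enumeration on small universes.

# The synthetic study

`default_study_scenario()` bundles the generator configuration the
package treats as its reference conditions:

* two conditions — baseline (`ND`) and differentiated (`AD8`) — with 2
  biological replicates each, each sequenced in both adapter
  orientations (`from_5p`, `from_3p`) as technical replicates: 8 samples
  of 10^5 35-color reads. The emulated study also had an intermediate
  time point; the scenario models the endpoint contrast, which is the one
  with reported significance, and the pipeline itself supports any number
  of conditions.
* ~150 expressed mature miRNAs with log-normal abundances (sdlog 1.6), two
  dominating at 30.2% and 13.8% of miRNA reads; a 5-member family rising
  from 1.1% to 4.9% of miRNA reads; 21 planted up-regulated miRNAs
  (log2fc 1.25–4.5, including the family and a novel arm) and 5 planted
  down (−1.3 to −2.1);
* a novel 3p arm absent at baseline (exactly zero reads) and at ~500 cpm
  after differentiation, its 5p arm below the abundance filter;
* a twin/decoy pair on opposite strands of one locus whose mature
  sequences differ at exactly one 3'-terminal base, the decoy planted at
  1/14 of the twin;
* class mixture over reads: ~44.5% human miRNA, 37% un-annotated
  (an intronic-style 21-nt locus plus degradation-like background
  windows), 8% transcript, 4.5% tRNA (all drawn from 5' tRNA halves,
  emulating 5'-tRFs), and small rRNA/snoRNA/piRNA/other fractions;
* isomiR end jitter of ±1–2 nt (70% exact ends), a linearly declining
  quality profile with Gaussian noise, and color errors injected at
  `min(10^(-q/10), 0.25)` per color (~1% on average);
* biological replicate variability: each biological replicate's
  abundances are the condition abundances perturbed by `2^N(0, 0.25)` and
  renormalized, shared by its two technical replicates. Without this
  term every high-count null miRNA shows a tiny but statistically
  detectable compositional shift (closure of the simplex), which no real
  library would resolve; 0.25 on the log2 scale is a modest
  between-culture variability that keeps strongly regulated features
  (|log2fc| ≥ 1.5) clearly detectable with two replicates.

Truth is recorded per source unit (condition abundances on a global
simplex, true compositional log2 fold changes, coordinates, arm) and per
read (origin unit, injected error count). All randomness derives from
one master seed through named substreams (reference, abundance,
biological replicates, reads, errors), so stages are independently
reproducible and outputs are byte-identical for a fixed seed. A separate
`structure_seed` can pin the reference and planted truth while the master
seed varies, which is how the validation suite averages estimates over
20 re-sequencings of one study.

**What passing tests do and do not show.** The generator emulates the
*statistical* structure of a SOLiD small-RNA experiment — skewed
abundances, quality-linked color errors, end jitter, adapter
read-through, opposite sequencing directions — on a toy genome with
non-overlapping features. It does not model ligation/cloning bias,
PCR duplication, genomic repeats or multi-mapping families,
cross-mapping between paralogous miRNAs, or instrument-specific noise
beyond the quality-linked error curve. Recovery results on it validate
the pipeline's correctness, not the biological accuracy of any
particular real-data analysis.

# Numerical and design choices

* Coordinates are 1-based inclusive everywhere in R structures, matching
  GFF3 and GenomicRanges convention (a 0-based half-open internal
  representation would be idiomatic in other ecosystems, not here).
* Quality values are raw instrument integers, one per color; no Phred
  rescaling. U→T conversion happens silently on every sequence ingest.
* The primer base is dropped before any matching; csfasta records carry
  it, the analysis never uses it beyond decoding.
* Degenerate inputs are defined: empty feature catalogs are valid
  (everything mapped becomes `non_annotated`); samples with zero miRNA
  reads get `NA` normalized values and are flagged; precursors without
  mature children yield coverage but `NA` arm statistics; an empty census
  match set reports missing quality summaries.
* The pipeline configuration file is YAML — the plain-text key-value
  format the R ecosystem reads natively — with every threshold defaulting
  to the analysis values (18/1/2 budget, 10^6 normalization, 300 cpm,
  alpha 0.05).
* Problem sizes used by the validation suite: matcher-oracle equivalence
  on 50 random ≤2.5 kb genomes × 200 reads; color-space algebra on
  10,000 random cases; moderated-t calibration on 2,000 null features;
  truth recovery on 20 re-sequencings of the default scenario at 10^5
  reads/sample; census behaviour over 50 seeds of a 3,000-read twin/decoy
  experiment. These sizes were chosen as the smallest at which the
  checked quantities are statistically stable.

# Known limitations

* No iterative 3'-truncation rescue of unmappable reads (whether the
  historical tool did this is unstated; it is deliberately not
  implemented), so long inserts with adapter-region errors stay
  unmapped.
* No SAM/BAM emission and no spliced or indel-aware alignment; the
  matcher targets contiguous small-RNA hits on toy-to-moderate
  references, not genome-scale alignment.
* The differential model is Gaussian on log cpm with equal-variance
  one-way structure; count-likelihood models (negative binomial GLMs)
  and multi-factor designs are out of scope.
* Seed-site scanning is site-type only: no context scoring, conservation
  branch lengths, or structural accessibility.
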