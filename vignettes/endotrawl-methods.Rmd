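---
title: "endotrawl: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{endotrawl: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`endotrawl` recovers and tracks minute (234–375 kb) denitrifying
endosymbiont genomes — *Azoamicaceae*-type symbionts of ciliates — in
metagenomes and amplicon time series. This vignette is the package's own
account of the science: the models and their assumptions, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the places where the design was genuinely open and a choice had to be
made. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The discovery funnel

Screening thousands of public metagenomes for a 300 kb genome is only
feasible with a cheap read-level triage ahead of assembly-scale work. The
funnel is: **prescreen reads → recruit contigs → score bin quality →
confirm presence by coverage**, and a dataset that fails an early stage is
never carried further (the pipeline short-circuits, which the tests assert
via an instrumentation counter).

### 1.1 BLAST Score Ratio prescreen

A read's similarity to a marker protein is measured by the BLAST Score
Ratio: the best local-alignment score against the marker divided by the
read's self-alignment score. Dividing by the self score normalizes away
read length and composition, giving a value in [0, 1] under any
diagonal-dominant scoring scheme.

In translated mode the read is translated in all six frames. We compute the
ratio *per frame* — `S(p_f, marker) / S(p_f, p_f)` for each frame
translation `p_f` — and report the best frame. Pairing raw and self scores
within a frame is a deliberate choice: a cross-frame self score (the
literal "read vs itself" maximum over frames) could exceed the aligned
frame's self score, so the ratio for an exact reverse-translated marker
fragment would not be exactly 1 and the [0, 1] bound would not be
guaranteed. The per-frame pairing makes both properties exact, and both are
asserted in the tests.

Screening is sequential: every read is scored against *tlcA* (the ATP/ADP
translocase, the symbiosis' hallmark energy-export protein, present in all
known family members); only datasets whose *tlcA* coverage clears the gate
are scored against *nosZ* (nitrous oxide reductase — note one described
species lacks it, which is exactly the failure mode the `fail_stage2`
verdict encodes). Marker coverage is estimated as
`passing reads × read length / marker nucleotide length` (3× the protein
length). The gate is **strictly greater than 5**.

Tunables: `bsr_min` (default 0.4 — the read must align over roughly 40% of
its length; the published threshold lives in supplementary material not
available here, so this is a configurable package default) and
`coverage_min` (default 5, from the published gate). A pooled-coverage mode
(both markers' reads over both markers' lengths) is provided but off by
default, since the published wording does not settle per-marker versus
pooled estimation.

### 1.2 Alignment engine

All scores come from one affine-gap local aligner (Gotoh recurrences,
gap of length L costs `open + L·ext`), implemented in C++ with three code
paths: full dynamic programming with traceback (reads, proteins, rRNA
genes), a linear-memory score-only batch used by the BSR machinery, and a
seeded path (exact k-mer index, candidate diagonals ranked by seed support,
ungapped Kadane extension along the diagonal, then gapped refinement on a
bounded window for queries up to `refine_max_len`). The seeded path never
reports a score above the full-DP optimum — it searches a restricted
space — and the test suite checks equality of the full path against an
independently written pure-R DP oracle on hundreds of random pairs.

Defaults are BLAST-like: nucleotide +2/−3 with gap 5/2; protein BLOSUM62
with gap 11/1. Tie-breaking is fixed (diagonal over vertical over
horizontal; first maximal cell in row-major order) so results are
reproducible to the byte. Coordinates are 0-based half-open everywhere
except the BLAST-style 12-column TSV, which is 1-based inclusive like the
format it mirrors.

Long queries (contigs) skip gapped refinement and keep the ungapped
extension. Under the generator's substitution-only error model this is
exact; on real indel-rich data it would understate scores, which is a known
limitation (§6).

### 1.3 Recruitment, circularity, synteny

A contig is recruited to a reference genome when it is **strictly longer
than 3 kb** (3001 bases pass, 3000 do not — the boundary is asserted in a
test) and its best hit spans ≥ `min_hit_columns` (default 1000) at
≥ `min_identity` (default 0.80). The published rule fixes only ">3 kb";
the column and identity floors are this package's defaults, chosen so that
a genuinely related contig (a few percent diverged) passes easily while a
random 20 kb contig cannot. Each contig is assigned to at most one
reference — the best score, ties to the lexicographically smaller
reference id — so congeneric references cannot double-bin a contig.

Circularity uses a proxy for assembly-graph closure, which is out of scope:
a single-contig bin whose prefix exactly equals its suffix over at least
`circular_overlap_min` (default 50) bases is closed, the longest such
repeat is reported, and the duplicated suffix is trimmed. The call is
invariant under rotation of the underlying circular genome, and 200 random
linear contigs produce no false closure in the Monte-Carlo null test.

The synteny audit exploits the family's strongly conserved gene order.
Bin and reference genes are anchored by best reciprocal protein hits (BSR
≥ 0.4 both ways); collinearity is the longest strictly order-preserving
anchor chain (longest increasing subsequence over reference order, both
orientations, the better taken) divided by the anchor count. Contigs
contributing no anchor to the chain are flagged as putative binning errors.
The LIS is checked against an exhaustive all-subsequences oracle on 12-gene
permutations.

### 1.4 Completeness, contamination, MIMAG tier

Completeness is the percentage of a family-specific single-copy marker set
found at least once among the bin's proteins; contamination is the
percentage found in two or more copies. Multi-copy markers count toward
completeness (the CheckM-like convention; the published computation is in
supplementary material, so the convention is declared here rather than
inferred). A bin protein counts for a marker only if that marker is its
best-scoring marker and the BSR is ≥ `bsr_min` — this prevents one protein
from satisfying several related markers. Percentages are printed to two
decimals, rounding half away from zero, which reproduces the published
54.55% (= 30/55) and 89.09% (= 49/55) exactly.

The bundled ORF caller exists so the package is self-contained (real
annotation was external in the source workflow): maximal ORFs from the
first ATG/GTG/TTG after an in-frame stop, genetic code 11, six frames,
origin-spanning ORFs handled on the doubled sequence for circular bins.
`min_aa` defaults to 100 residues — marker genes are longer, and the
default keeps random short ORFs from inflating the protein set.

Tiers follow the MIMAG community standard's numeric criteria: high iff
completeness > 90 and contamination < 5 and all of 5S/16S/23S detected and
≥ 18 tRNAs; medium iff completeness ≥ 50 and contamination < 10; else low.
tRNA detection is intentionally not implemented — `trna_count` is an input
supplied by external annotation and defaults to 0, which blocks the high
tier unless provided.

Species assignment from 16S uses the best-scoring reference and demands
identity **strictly above 98.7%** (the standard species-level 16S
threshold); a constructed query at exactly 98.70% identity is asserted to
remain unclassified.

### 1.5 Presence from breadth of coverage

For mean depth `d`, the expected fraction of a genome covered by at least
one read under near-uniform placement is `1 − exp(−0.883·d)`; the 0.883
coefficient is the published empirical decay constant (idealized uniform
placement would give 1.0, so the curve sits slightly below the naive
expectation, absorbing real-world mapping unevenness). A genome is called
present when observed breadth is within `tolerance` (default 0.15) of the
expectation.

"Within 15%" is read as a **relative, one-sided lower bound** by default
(`b ≥ 0.85·b_exp`): breadth above expectation indicates unusually even
coverage, which is evidence for presence, not against it. The literal
two-sided band is retained as an option because the published wording does
not disambiguate. Detection requires `d > 0` (avoiding 0/0; the ratio is
reported as 0). Depth counts aligned reference bases only, so clipped read
ends do not inflate it. The calibration property — uniform placement at
depths 0.5–5 is detected ≥ 95% of the time — is exercised with 200
replicates per depth in the acceptance suite.

## 2. Time-series analyses

Counts tables (samples × taxa, ISO dates, plant labels) are converted to
per-sample relative abundances; all-zero samples yield zero rows and are
flagged rather than dropped. Families aggregate member species by
summation. Detection fractions are percentages of sampling points with
count ≥ `min_count` (default 1), printed to one decimal half away from
zero — 132 of 268 prints 49.3, 123 of 626 prints 19.6. The fall–winter
window is 21 September through 21 March, both boundaries inclusive,
computed by month/day comparison so leap years need no special casing; an
exhaustive sweep over a leap and a non-leap year checks every day is
labelled exactly once.

**Bloom calling.** A bloom is a transient excursion far above a taxon's
long-run baseline. The series is first smoothed with a centered rolling
mean of width `window` (default 5 samples); a bloom is a maximal run where
the smoothed series exceeds `median + k_mad·MAD` (both statistics over the
smoothed series, MAD with the usual 1.4826 constant, `k_mad` default 5),
with the additional requirement that the raw peak reach `min_peak`
(default 1e-4, i.e. 0.01% relative abundance). The smoothing window is the
design choice that makes the detector usable: without it, sampling noise
fragments one real multi-week bloom into several events and lone
single-sample spikes fire false alarms, and no threshold setting fixes
both. The `min_peak` floor is a detection-limit parameter: it is meaningful
for taxa whose baseline sits below 0.01% — precisely the regime of these
symbionts in routine amplicon surveys — and inert for abundant taxa.
A constant series produces no blooms (MAD 0, nothing strictly above the
median).

## 3. The synthetic world

The generator emulates the study system so every stage has ground truth:

* **Genomes**: one circular sequence of `genome_length` bases (default
  300,000, inside the family's 234–375 kb range) carrying one
  reverse-translated copy of each catalog protein in catalog order on the
  forward strand. Reverse translation samples synonymous codons with the
  seeded RNG (genetic code 11) and appends a stop. Each gene is preceded by
  a 22 nt cassette containing stop codons in all six frames and no start
  codon on either strand; this guarantees the planted genes are maximal
  ORFs at exactly their recorded coordinates, making the ORF caller's
  ground-truth test exact. Spacer fill is uniform random DNA.
* **Marker catalog**: `tlcA` and `nosZ` at 500 aa (the real proteins are
  ~500–640 aa) plus 55 completeness markers of 120–250 aa. The
  55-marker default makes single markers worth 1/55 of completeness,
  matching the published two-decimal percentages. The real marker set is in
  unavailable supplementary material, so the size is a config default, not
  a formula constant.
* **Related species**: seeded substitutions at an expected per-base
  divergence; gene order, lengths and coordinates unchanged — the family's
  conserved synteny, in idealized form.
* **Reads**: multinomial genome assignment, uniform starts (wrapping the
  origin for circular genomes via the doubled sequence), uniform strand,
  substitution-only errors, constant Q40 qualities. No indels, chimeras or
  quality decay — this keeps mapping and alignment oracles exact, and is
  the main respect in which a green test understates real-data difficulty.
* **Assemblies**: seeded random tilings into `n_fragments` contigs of at
  least `min_len`; circular mode appends a wrapped terminal overlap so
  circularity detection has its planted positive control.
* **Count tables**: negative-binomial counts around per-taxon baselines
  (`variance = mu + dispersion·mu²`, dispersion default 0.3 — the
  overdispersion typical of amplicon counts), bloom intervals multiplying
  the mean by a fold factor, zero dispersion degenerating to deterministic
  rounded baselines. The acceptance world spreads ~50,000 reads per sample
  over 20 background taxa (stable totals, as sequencing depth is roughly
  fixed in practice) with the symbiont baseline below the 0.01% floor.

Determinism is a contract: every generator is a pure function of its
arguments and seed, asserted byte-for-byte in the tests. The end-to-end
acceptance scenario — a 300 kb genome at depth 10 with 1% error among 20
background genomes of 20 kb at depth 3 — is the package's stated world;
background size and depth are not published quantities, so they were chosen
once at desk scale and frozen.

## 4. Numerical choices

* Percent formatting: half-away-from-zero at 2 decimals (completeness,
  contamination) and 1 decimal (detection fractions), matching the printed
  values the package reproduces.
* Alignment ties: diagonal > vertical > horizontal; first maximal cell in
  row-major order.
* `expected_breadth` is evaluated directly as `1 − exp(−k·d)`; the test
  oracle re-derives it by scaling-and-squaring a short Taylor series and
  demands agreement to 1e-12.
* Degenerate inputs: empty read sets fail stage 1 with coverage 0; an
  empty contig set recruits nothing (not an error); zero-depth profiles are
  never detected and report ratio 0; zero self-score reads (no translatable
  frame) raise an error rather than returning a ratio.
* The FASTQ reader names the offending line on malformed records;
  duplicate ids are rejected in all sequence inputs.

## 5. What a green suite establishes — and what it does not

The tests establish that the implementation is faithful to its stated
models: alignment equals an independent oracle, the BSR funnel triages a
planted community correctly, recruitment recovers exactly the true
fragments against a random background, completeness arithmetic is exact
over the whole sweep, the detection model is self-calibrated, and planted
blooms are recovered with the stated sensitivity and specificity. They do
not establish performance on real data: real reads carry indels and
quality decay, real assemblies chimeras and strain mosaics, real references
diverge non-uniformly, and real amplicon tables have compositional and
batch structure the negative binomial does not capture. The published
field-scale numbers (hundreds of WWTP datasets, 16 real MAGs) require
external sequencing data and are out of desk-scale scope by design.

## 6. Known limitations

* Substitution-only error model; no indel-aware extension beyond affine
  gaps in the refinement window; long contigs rely on ungapped extension.
* No E-value statistics — thresholds are score-ratio and identity based.
* tRNA counting is delegated to external annotators.
* The circularity proxy (exact terminal repeat) cannot see closure
  evidence that lives in the assembly graph rather than in the contig
  sequence.
* Bloom calling assumes roughly regular sampling; strongly irregular
  intervals would make the rolling-mean window heterogeneous in time.
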