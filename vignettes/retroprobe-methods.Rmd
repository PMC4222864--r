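---
title: "retroprobe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{retroprobe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroprobe)
```

This vignette is the package's own account of its methods: the models and
procedures, the parameters that matter and why they default as they do,
what the synthetic-data generator does and does not emulate, and the
design decisions taken where the problem left genuine freedom.

## 1. Identifying RE-reporting probes

### Mapping model

Probes are short (typically 25-mer) oligos. We localize each probe by
**full-length, ungapped** comparison against both strands of every
chromosome. A placement qualifies when the number of identical bases is
at least `ceiling(min_identity * plen)`; the default `min_identity =
0.95` means a 25-mer tolerates exactly one mismatch (24/25 = 96%) and
never two (23/25 = 92%). The identity denominator is always the full
probe length, so partial-length placements cannot qualify by shortening
the alignment.

This deliberately replaces a seed-and-extend short-sequence aligner. At
95% identity on 25–60-mers, gapped placements that would still pass the
threshold are edge cases, while the ungapped contract is *exactly*
testable: the package's test suite compares `map_probe` against a
brute-force scanner that counts mismatches at every genomic offset on
both strands, and requires identical hit counts and identities for every
probe. Consequences of the contract:

* `numhits` counts qualifying placements only (distinct
  chromosome/offset/strand triples), not every raw local alignment.
* The reported hit maximizes identical bases; ties break
  deterministically on lowest chromosome name, then start, then strand
  (`+` before `-`).
* Ambiguity bases (`N`) in the genome never match; probes containing
  non-ACGT characters are rejected at input.
* Lowering `min_identity` can only add placements (monotonicity is
  property-tested).

Sequence scanning itself is delegated to `Biostrings::matchPattern`
(`max.mismatch`, `fixed = TRUE`); matches overhanging chromosome ends are
discarded to preserve the full-length contract.

### Classification and chemistry

A mapped probe reports RE expression iff its best placement is **strictly
contained** in a single repeat-masked interval and its orientation
reports *sense* transcription of the element:

| platform chemistry | example | rule |
|---|---|---|
| antisense cRNA | 3' expression arrays | probe strand == repeat strand |
| sense cDNA | gene/exon ST arrays | probe strand != repeat strand |

Chemistry is an explicit input (manifest pragma or argument), never
inferred from a platform name — inference tables go stale. Strict
containment means a probe overhanging a repeat boundary by one base does
not classify; adjacent fragments of the same element in the repeat
annotation are *not* merged before the test (the simplest faithful
reading; merging fragmented records of one element is a recognized open
choice that would only widen the eligible intervals).

### Genomic context

For uniquely mapped probes we record the nearest protein-coding genes
chromosomally 5' and 3' of the probe — direction is by coordinate,
irrespective of gene strand — and the distance to the nearer of the two
(0 when the probe overlaps a gene). Distances are measured from the probe
interval, not the probeset envelope, because the filter text names the
probe. For probes mapping to multiple loci, every annotation field that
presumes one genomic context (placement, repeat identity, neighbors) is
omitted; only the probe identity, probeset, length and hit count survive.

`intragenic_position_bins` expresses each intragenic or near-genic
(<= 1 kb) probe's midpoint as a fraction of gene length measured 5'→3'
along the gene's own strand, clamped to [0, 1] (upstream probes land in
the first bin, downstream in the last) and binned in tenths to
standardize for gene size.

### Enhanced filtering

The filter retains an RE-reporting probe iff:

1. it maps uniquely (`numhits == 1`),
2. its gene distance strictly exceeds `min_gene_distance` (default
   1000 bases: 1000 fails, 1001 passes), and
3. strictly more than `min_probeset_re_fraction` (default 0.75) of its
   probeset's probes report RE expression — so 9/11 passes while 8/11
   and exactly 3/4 fail.

Both thresholds are strict inequalities by the literal reading of the
method ("> 1 kb", "> 75%"), and both boundary cases are unit-tested. The
fraction's denominator is *all* probes of the probeset in the platform
manifest, including unmapped ones. The uniqueness requirement is applied
per probe; whether the original procedure required the whole probeset to
be uniquely placed is ambiguous, and the per-probe reading is the less
destructive one. Filtering is monotone (tightening any threshold never
adds a probe) and invariant to row order; both are property-tested.

## 2. Coordinate conventions

Internally every interval is 0-based half-open, with conversion confined
to the I/O layer: RepeatMasker `.out` and GTF are 1-based inclusive on
disk (`.out` uses `C` for the minus strand), BED is already half-open,
and the 18-column annotation CSV is written 1-based inclusive so it is
directly comparable with published probe annotation files. A single
internal convention eliminates off-by-one drift between formats;
round-trips through every writer/reader pair are tested.

## 3. Expression statistics

### Preprocessing

Probe intensities are background-corrected under the signal-plus-noise
convolution model (observed = exponential signal + normal noise) using
limma's normal-exponential machinery (saddle-point parameter estimates);
the returned value is the posterior expected signal, which is strictly
positive and monotone within an array. The contract tested is the
transform's shape and its simulation behavior — on data drawn from the
model with known signal, corrected values sit closer to the truth than
raw ones. Arrays with zero variance make the model degenerate and are
refused with a pointer to the skip flag. Quantile normalization (limma,
`ties = TRUE`) forces every array's sorted vector to the across-array
mean of order statistics; it is idempotent and checked against an
independent mean-of-order-statistics oracle. Log2 transformation follows.

### One-step Tukey biweight

Probesets are summarized per sample by

$$T = \frac{\sum_i w(u_i)\,x_i}{\sum_i w(u_i)}, \qquad
u_i = \frac{x_i - M}{cS + \epsilon}, \qquad
w(u) = \begin{cases}(1-u^2)^2 & |u| < 1\\ 0 & \text{otherwise}\end{cases}$$

with $M$ the median, $S$ the unscaled median absolute deviation
(`median(|x - M|)`, no 1.4826 consistency factor), and the fixed
constants $c = 5$, $\epsilon = 10^{-4}$ from the classic array
summarization algorithm. $\epsilon$ only guards the division when
$S = 0$; for tight data all $|u_i| \ll 1$ and $T$ approaches the
arithmetic mean, while any point with $|u| \ge 1$ has *exactly* zero
influence. The implementation is verified against an independently coded
straight-line transcription of the formula to $10^{-12}$ on 10,000
random vectors.

### ANOVA selection

Per probe we fit the fixed-effects model
`value ~ eliminated factors + factor of interest` and test the factor of
interest by its extra sum of squares after the eliminated terms
(sequential ANOVA; implemented with shared QR projections across probes,
and spot-checked against `anova(lm(...))`). P values are raw by default,
mirroring raw-p thresholding practice for these selections; an optional
Benjamini-Hochberg flag is available. Aliased designs (factor of
interest confounded with a blocking factor) are refused by rank
comparison of the two design matrices.

Calibration is tested by simulation: on null data (1000 probes, 3
tissues x 3 replicates) the retained fraction at alpha = 0.01 must fall
inside the binomial 95% band. For power, effect probes carry graded
tissue means 0/3/6 residual SDs — the most generous honest reading of a
"3-SD between-tissue shift" (each adjacent pair separated by exactly
3 SD). Note the exact noncentral-F power of this design
(`pf(qf(.99, 2, 6), 2, 6, ncp = 54, lower = FALSE)`) is 0.957, so at
these sizes roughly 1 in 25 such probes is legitimately missed; the
suite's corresponding check documents this ceiling.

### Concordance of lone RE probes

For probesets containing exactly one RE-reporting probe and at least two
others, the RE probe's values are compared per condition level (Welch t
test across replicate samples) against the biweight summary of the
remaining probes, with Holm-Bonferroni correction across the levels of
each probeset; the probeset is concordant when every corrected p exceeds
0.05. Degenerate comparisons (both sides constant) are scored p = 1 when
means agree and p = 0 otherwise, so a duplicated probe is concordant by
construction.

### Nearest-gene regression

One point per RE probe and sample of the selected tissue: probe value
against the biweight summary of its nearest protein-coding gene (the
nearer of the 5'/3' neighbors; ties go 5'), with points whose gene is
absent from the platform omitted and counted. Least-squares lines are
fitted per top-level repeat class, reporting slope, r, r², and p. The
per-(probe, sample) point definition is a documented choice; regressing
per-probe means across samples is the plausible alternative and would
only reduce the number of points.

### Hierarchical clustering

Average-linkage agglomeration on Pearson correlation distance (1 − r),
the conventional default when no metric is specified. Items are sorted
by identifier before clustering, making leaf order deterministic and
memberships invariant to input order; constant items (undefined
correlation) are placed at distance 1 from everything, with a warning.

## 4. The synthetic-data generator

The fixtures stand in for full genome builds, repeat libraries and
public expression accessions, at a scale where every decision boundary
can be planted and checked exactly.

**Genome** (default 3 x 60 kb): random sequence with 42 planted repeat
instances (ERVK, ERV1, ERVL-MaLR, L1, B2 families on both strands; one
family planted as three identical copies) and 11 genes (10
protein-coding, 1 lincRNA) laid out with explicit gaps so that every
planted probe's gene distance is known by construction — including
repeats at exactly 1000 and 1001 bases from a gene, and repeats within
1 kb of genes. A lincRNA adjacent to retained repeats verifies that
non-coding genes are excluded from distance calculations.

**Platform** (89 probes): probesets at 9/11, 8/11 and exactly 3/4 RE
fractions; an all-RE probeset including one probe carrying a single
mismatch (still >= 95% identity); single-probe probesets at the two
exact distances; multi-copy probes hitting all three identical repeat
copies; wrong-orientation probes (reverse complements of qualifying
probes); boundary-overhang probes extending one base past their repeat;
genic and unmappable probes; per-gene probesets providing nearest-gene
summaries; and a probeset with one RE probe among three co-regulated
genic probes for the concordance test. Every probe carries a truth label
(category, expected hit count, expected classification and retention),
and the end-to-end contract — map → annotate → filter recovers exactly
the planted retained set, for both chemistries — is the package's
central acceptance property.

**Expression** (9 samples: 3 tissues x 3 experiments): each gene gets a
baseline ~ N(8, 1), a preferred-tissue effect of 2 log2 units, an
experiment (batch) offset of 0.5 per step, and probe-level noise
(SD 0.5). RE probes share 30% of their variance with their nearest
gene's standardized signal; one probe is shifted +4 log2 units as a
planted outlier for the summarization. A linear-scale export supports
the background-correction path.

A single integer seed drives one independent RNG stream per
sub-generator, so extending one plan never perturbs the others, and all
derived seeds stay within 32-bit integer range.

For parameter-recovery checks of the regression, `simulate_coregulation`
plants the shared-variance fraction *exactly in sample*: the noise
vector is residualized against the gene signal and rescaled so the
sample r² equals the planted fraction identically. With stochastic
mixing the Monte-Carlo SD of r² at 500 points is ~0.025 — of the same
order as the recovery tolerance — so exact planting makes the check
measure the estimator rather than noise in the truth. The demo
expression generator keeps plain stochastic mixing, since realism
matters more than exactness there.

**What the fixtures do not emulate**, and hence what passing tests do
not show about real data: repeat sequence evolution and family internal
structure (planted repeats are random sequence), cross-hybridization
chemistry and probe affinity biases, fragmented repeat-masker records of
single elements, transcript-isoform structure (gene context uses gene
bounds, not transcript bounds), and realistic probeset-to-transcript
design. Perfect precision/recall on fixtures validates the decision
logic, not the biological error rate on a real platform.

## 5. Problem sizes and determinism

The bundled checks run at deliberately small scale — 20 random 2 x 10 kb
genomes for the mapper-oracle comparison, exhaustive 1- and 2-mismatch
variants of a 25-mer (325 mappings), 10,000 random vectors for the
biweight oracle, 1000 probes for ANOVA calibration and power, 500 points
per shared-variance condition, and the 89-probe demo platform on the
3 x 60 kb genome. These sizes keep the whole suite in the minutes range
while leaving each statistical check enough resolution for its stated
tolerance. The full pipeline is deterministic given its configuration:
reruns with the same seed produce byte-identical artifacts, verified by
checksum comparison.

## 6. Known limitations

* Ungapped full-length mapping diverges from seed-and-extend aligners
  for indel-containing placements; at the default identity threshold
  this affects only pathological probes.
* Nearest-gene context uses gene bounds; a probe 1 kb from an annotated
  gene terminus can still sit inside an unannotated extended transcript.
* The concordance test requires >= 2 replicates per condition level and
  >= 2 non-RE probes per probeset; probesets failing either are skipped
  (with a warning), not scored.
* Batch structure is handled only as a fixed blocking factor in the
  ANOVA; no empirical-Bayes batch correction is provided.
* Coverage percentages count repeat *instances* from the annotation as
  given; fragmented instances of one element inflate the denominator.
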