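---
title: "Methods: repeat-read screening and telomere phenotype statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-read screening and telomere phenotype statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teloscreen)
```

## The problem

Proteins that bind telomeric chromatin leave a simple signature in their
ChIP-seq libraries: an excess of reads containing the telomeric tandem
repeat. teloscreen turns that signature into a screening statistic — the
fraction of a sample's reads that contain six tandem copies of `TTAGGG`
as an exact substring — and ranks a cohort of protein targets by it, the
way a cohort of several hundred ENCODE ChIP-seq datasets can be screened
for telomere-associated proteins (TAPs). The package also implements the
downstream statistics with which candidate TAPs are phenotyped in cells:
qPCR relative telomere length (T/S), nonparametric and parametric group
comparisons, and per-nucleus focus colocalization counts of the TIF
(telomere dysfunction–induced focus: DNA-damage focus on a telomere) and
APB (ALT-associated PML body: PML body on telomeric DNA) kind.

Everything runs on synthetic inputs with exactly known ground truth, so
each statistic can be validated end to end before it ever touches real
data.

## The screening statistic

For a motif specification `(unit, copies, strand_mode)` the search set
is the concatenated motif and, with `strand_mode = "both"`, its reverse
complement; a self-reverse-complementary motif is searched once. For the
default `(TTAGGG, 6, both)` the set is the G-strand 36-mer and the
C-strand `(CCCTAA)6`. A read is repeat-positive iff a search string
occurs as an exact contiguous substring of the uppercased read — no
mismatches, and `N` never matches, so a single ambiguous base inside the
site breaks the match. Classification is boolean per read; overlapping
or repeated occurrences in one read count once.

The per-sample statistic is

$$\mathrm{ratio} = \frac{\#\{\text{reads containing the motif}\}}
                        {\#\{\text{denominator reads}\}}$$

For FASTQ input every read is in the denominator. For SAM/BAM input the
denominator defaults to primary mapped records (unmapped, secondary and
supplementary records excluded; `all_reads` mode keeps unmapped primary
records). The mode used is recorded in every result row, because "total
reads" and "total mapped reads" genuinely differ and published screens
are often ambiguous about which was used. Both strands are searched by
default since shotgun reads sample both strands of telomeric DNA;
`forward_only` reproduces a literal G-strand-only search.

A sample passes QC when its denominator holds at least `min_reads` reads
and its modal read length is at least `min_read_length`. The
`"encode-k562"` preset (20 million reads, 37 bp) reflects screening
full-scale public ChIP-seq libraries; 37 bp is the shortest read that
can contain the 36-mer with one flanking base. The `"desk"` preset keeps
the same length gate but a 1000-read depth gate so that small simulated
cohorts exercise the QC machinery rather than trivially failing it. A
sample with zero denominator reads gets an undefined (`NA`) ratio and a
QC failure — never a silent 0.

## Cohort aggregation and candidate calling

Replicate ratios are collapsed per target by the mean (median and max
are available; the mean is the least surprising collapse of a small
number of replicates and the choice is exposed rather than hidden). The
cohort distribution is summarized with linear-interpolation quartiles
(`quantile(type = 7)`) — stated explicitly because Tukey fences move
with the quartile convention. A target is an outlier candidate when its
score exceeds `Q3 + 1.5 * IQR`; a `mean + 3 sd` z-score rule is
available. Ranking sorts by descending score with lexicographic
tie-break, so results are deterministic. When the manifest carries a
`class` column, histone-marker samples contribute to the distribution
summary but are excluded from ranking and candidate calls, mirroring
screens that pool chromatin marks for context but nominate proteins.

## Relative telomere length

T/S follows the standard monochrome-multiplex qPCR transform: per
sample, `dCt = Ct(telomere) - Ct(albumin)` and `T/S = 2^-dCt`. Only this
transform is implemented; standard-curve and PCR-efficiency machinery is
upstream wet-lab territory, and no additional reference-sample
normalization is applied. T/S equals 1 at equal Ct values, is invariant
under shifting both Ct values jointly, and `log2(T/S) = -dCt` exactly.
Ct values outside (0, 45) cycles are flagged, not rejected.

Distribution comparisons use the Wilcoxon rank-sum test. For combined
sample size up to 10 (configurable) the p-value comes from exact
enumeration over all $\binom{n}{n_A}$ assignments of midranks to group
A, which is correct under ties; beyond that, the normal approximation
with midrank tie correction and continuity correction is used. The
enumeration threshold of 10 keeps the exact path at ≤ 252 splits —
negligible cost — while sizes above it are comfortably in normal-
approximation territory. The one-sided direction is always supplied by
the caller; the package does not guess which group is expected to be
longer. Welch's t test and one-way fixed-effects ANOVA (via `stats`)
cover mean comparisons; degenerate zero-variance inputs return the
closed-form limits (t = 0, p = 1 for identical constant groups; p = 0
when constant groups differ) rather than erroring mid-pipeline.

## Focus colocalization

Coordinates are 2D (microscopy projections) in an arbitrary common
unit. Pairwise colocalization uses one-to-one mutual nearest-neighbor
matching: foci a and b match iff each is the other's nearest
cross-channel focus and their distance is at most the caller-supplied
threshold. Mutual-NN was chosen over greedy-by-distance because it is
deterministic, invariant to input order, and encodes "a focus
colocalizes with at most one partner"; ties in nearest-neighbor distance
are broken toward the lowest index after a stable sort by (x, y). With
three channels, a matched pair extends to a triple iff an unclaimed
third-channel focus lies within the threshold of the pair midpoint. The
threshold has no default: imaging criteria are instrument- and
magnification-specific, so it must be stated in the table's own units.

The TIF-style ratio divides each nucleus's colocalized count by its
telomere-channel focus count and averages per group (the reference
channel is explicit; APB-style ratios use the same convention). A pooled
`sum(n_coloc)/sum(reference)` variant is available since published
per-group ratios are sometimes pooled rather than averaged. Cofoci
histograms report the fraction of nuclei per count bin with default bins
0, 1–4, 5–8, 9–10, >10. Two positive-cell fractions are compared with
the standard 2×2 chi-squared test (no continuity correction by default,
Yates optional).

## What the simulators emulate — and what they do not

`generate_reads()` plants the full motif at a uniform valid offset with
random flanks (exercising matches at read ends), assigns a configurable
fraction of planted reads to the reverse-complement strand, and
rejection-samples background reads until motif-free on both strands.
Rejection sampling makes the planted count the *exact* repeat-read
ground truth — a chance 36-mer occurrence in random sequence has
probability ~\(4^{-36}\) per position, negligible but not zero, and
exactness is worth the cheap check. `exact_count` mode (default) plants
exactly `floor(f * n)` reads so ratio recovery is an exact test;
`bernoulli` mode gives binomial scatter for stochastic checks. FASTQ
qualities are constant `I` because the screen never reads them.
Deliberately not emulated: base-quality and sequencing-error models,
adapters, genome-derived background, paired ends. Passing tests
therefore demonstrate correctness of the counting and statistics, not
robustness to sequencing artifacts — on real data, sequencing errors
can only break exact 36-mer matches, biasing ratios downward uniformly
across samples.

`generate_cohort()` gives every sample its own RNG stream derived from
`(master seed, sample index)`, so cohorts are reproducible even if
samples are generated in parallel or in any order. `generate_ct_table()`
adds independent Gaussian noise to both Ct values, making sample T/S
lognormal around `2^-offset` (group means at zero noise are exact).
`generate_foci()` plants `floor(colocalized_fraction * min(channel
counts))` shared anchors per nucleus with independent per-channel
Gaussian jitter; at zero jitter recovered counts equal planted counts
for any threshold below the minimum spacing of the uniform background
foci.

## Numerical and design choices

* Quartile convention: linear interpolation (`type = 7`); fences and
  outlier calls inherit it.
* Wilcoxon exact/approximate switch at combined n = 10; both paths
  validated against independent enumeration and `wilcox.test`.
* Matching determinism: stable (x, y) sort, lowest-index tie-break,
  `which.min` first-minimum semantics.
* Degenerate inputs: empty read files, zero-reference nuclei and
  zero-variance groups yield flagged `NA`s or closed-form limits, never
  silent zeros.
* Problem sizes in the validation suite: the exact-recovery and
  reverse-complement checks use 20,000–50,000 reads of length 50; the
  candidate-recovery study 20 targets × 3 replicates × 10,000 reads over
  10 seeds; the bernoulli-consistency study 100 seeds × 50,000 reads;
  the type-I-error study 1000 null replicates of 200 + 200 values.
  These sizes are large enough that every recovery is exact or within
  stated binomial tolerance, and small enough to run on a laptop in
  minutes.

## Known limitations

Mismatch-tolerant repeat matching, telomere-length estimation from read
content (TelSeq-style calibration), per-position coverage, image
segmentation and intensity-based colocalization coefficients are out of
scope. Mutual-NN matching is conservative relative to maximum-cardinality
matching on pathological geometries (chains of nearly equidistant
foci); the tests assert the bound explicitly. The screen performs no
duplicate-read removal and no input/control normalization; both can
matter on real ChIP libraries and should be handled upstream.
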