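---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alureg)
```

This vignette is the package's own account of the statistics it
implements, the parameters that matter, and the design choices made
where more than one defensible option existed. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Feature-class model

A TE locus is classified against each transcript of each gene into
exactly one of five classes, by precedence `exon` > `intron` > `up1k` >
`up10k` > `up50k`. The three upstream classes are *disjoint annuli* —
(0–1 kb], (1–10 kb], (10–50 kb] upstream of the TSS, strand-aware —
rather than nested windows. Disjointness is what makes per-class
position counts additive: the per-class tallies of a study sum exactly
to the total number of positions, which nested windows would
double-count. A locus spanning a shell boundary is placed by its
minimum edge-to-TSS distance; this is deterministic and equivalent to
classifying every base of the locus and taking the most specific class,
which is how the test suite's independent per-base oracle checks the
interval arithmetic (on toy genomes of ≤ 10 kb, every TE × transcript
pair is verified base by base). Per gene, classes are unioned across
transcripts, which is how combinations like "intron + up50k" arise.
Downstream regions and bodies of other genes are deliberately ignored.

Coordinates are 0-based half-open (BED convention) everywhere inside
the package; conversion to 1-based inclusive happens only where scan
hits are reported.

## Correlation screen

Counts are normalized by median-of-ratios size factors (the geometric
mean reference excludes features with any zero count) and transformed
as `log2(count / factor + 1)`. A regularized-log transform with
shrinkage would differ mainly for very low counts; Pearson r on
desk-scale data is insensitive to that difference, so the package uses
the explicit, dependency-free transform and documents it rather than
reimplementing shrinkage estimators.

For each tested (TE, gene) pair, r and its two-sided t-test p-value
(`t = r·sqrt((n−2)/(1−r²))`, n − 2 df) are computed three times: all
samples, controls only, cases only. Benjamini–Hochberg adjustment is
applied *within each group family across all tested pairs*, separately
for the cis set (assigned pairs) and the trans set (all DETE × DEG
pairs); the group-wise families match how per-group significance is
reported. Zero-variance features yield undefined correlations and are
excluded from the family denominator; groups smaller than `min_n = 3`
samples yield missing values. Significance defaults to adjusted
p < 0.05.

Trans results are summarized per TE element (a TE is "active" in a
group if it appears in ≥ 1 significant pair); the overlap algebra
(shared, case-only, control-only) satisfies the conservation identities
|shared| + |only_case| = |case| and |shared| + |only_ctrl| = |ctrl| by
construction, and the test suite asserts them. Panel enrichment is the
upper-tail hypergeometric probability; the background size N is always
an explicit argument because enrichment is meaningless without it.

## Consensus, conservation and PWM scanning

Repeat arms within a family are near-identical, so instead of a full
progressive multiple alignment (whose tool and parameters would
themselves be free choices), each sequence is globally aligned to a
family reference (match +1, mismatch −1, gap −2 per base) and projected
onto reference columns: insertions relative to the reference are
dropped (their count is recorded), deletions appear as gaps. The
projection is deterministic, testable against an exhaustive-enumeration
oracle for short sequences, and keeps every profile in a common
coordinate frame. Its cost is that lineage-specific insertions are
invisible — acceptable when the object of interest is the conserved
promoter region of the reference frame.

Per column, the consensus base is the gap-excluded modal base
(alphabetical tie-break), conservation is the modal frequency, all-gap
columns get consensus `N` and conservation 0, and columns covered by
fewer than half the rows are flagged. Conserved regions are maximal
runs of ≥ `min_run = 5` columns where DE conservation exceeds non-DE
conservation by ≥ `delta`. The default `delta = 0.05` is calibrated
a priori from the generator's design: mutation rates of 0.02 inside vs
0.10 outside the conserved window produce a modal-frequency gap of
about 0.08, and 0.05 sits midway between that signal and zero, several
binomial standard errors away from both at a few hundred sequences.

PFM → PWM conversion follows the convention behind JASPAR relative
scores: `w(b,i) = log2(((c(b,i) + p·bg_b)/(N_i + p))/bg_b)` with total
pseudocount `p = 0.8` distributed by the background (uniform by
default; both are arguments). The relative score of a site is
`(s − s_min)/(s_max − s_min)` where `s_min`/`s_max` are the column-wise
minimum/maximum sums, so it is invariant to per-column constant shifts
(asserted in tests). Scanning scores every window on both strands;
minus-strand hits report forward 1-based inclusive coordinates and the
reverse-complement site text (the site as it matches the matrix). The
threshold comparison is `≥ 0.8`, treating the boundary as a hit.
Scanning real JASPAR CORE matrices requires the matrix files on disk
(`jaspar_fetch()` downloads them once); the package redistributes no
JASPAR data.

## COBRA quantification

The six band intensities A–F of a two-CpG COBRA assay enter five fixed
formulas (see `?cobra_percentages`). The formulas imply the band roles:
A is the fully unmethylated pattern band, F the fully methylated one,
C and D the two partial patterns, and B and E methylated-site fragment
bands satisfying B = D + F and E = C + F in an ideal gel. Under that
generative band map the formulas are the exact algebraic inverse of the
model: pattern percentages recover the molecule pattern fractions
exactly, and %mC equals the methylated-CpG fraction (each molecule
carries two CpGs; the numerator counts C + D + 2F of them). This
identity is what turns the formulas into a parameter-recovery test.
Pattern closure (the four percentages sum to 100) and invariance to
rescaling all six bands hold algebraically and are asserted over 10^5
random band sets.

Interassay normalization multiplies each metric by the ratio of a
reference control-line profile to the batch's own measurement of the
same control, then renormalizes the patterns to 100 — the simplest
scheme consistent with using a fixed cell line as an inter-gel anchor;
it is exposed as a plain function so an alternative can be swapped in.
Technical duplicates are averaged after percentage computation, and
pairs disagreeing by more than 10 percentage points on any metric are
flagged. Locus-specific per-CpG methylation is the digested fraction
`100·digested/(digested + undigested)`, since after bisulfite
conversion and PCR the restriction site survives only where the CpG was
methylated.

Group comparisons use the pooled-variance two-sample t test (two-sided)
with Cohen's d = mean difference over pooled SD; a zero pooled SD
leaves d undefined and is flagged rather than fabricated. ΔΔCt folds
are `2^−ΔΔCt` exactly. Phenotype association reports raw Pearson r, p
and the per-cell pairwise-complete n, without multiple-testing
correction — appropriate for small descriptive phenotype panels and
recorded in the result's `adjusted = FALSE` attribute; cells with fewer
than 3 complete pairs are masked.

## The synthetic-data generator

The generator is first-class, tested code whose defaults *are* the
study conditions the package targets: 21 + 21 count samples; 1000
TE–gene pairs of which 5% are truly coupled at target Pearson r = 0.8;
negative-binomial counts (single dispersion 0.05, mean log2 expression
8); a 130 bp reference arm with a 9-mer promoter motif inside a
40-column conserved window mutated at 0.02 per base (motif positions at
0.005) against a 0.10 background over 500 sequences per set; a 7 + 6
COBRA pilot with group pattern probabilities in the range typical of
cortical tissue, 10^4 molecules per assay and 5% lognormal band noise
measured in duplicate; and clinical scores coupled to %mC at theoretical
r = 0.7. One global seed drives fixed per-generator sub-streams
(offsets +101 … +505), so identical configurations are byte-identical
on disk and each generator can be re-run alone.

Two couplings deserve notes. First, counting noise attenuates latent
correlation: on the log2 scale a count with mean μ and dispersion φ
adds variance ≈ (1/μ + φ)/ln(2)², so the latent factor correlation is
inflated by that factor (capped at 0.995) to make the *observed*
log-scale r of a linked pair land near the target; the calibration test
confirms the mean recovered r lies in [0.7, 0.9]. Second, the reference
carries the intact promoter motif (as the ancestral element would) and
the non-DE template carries a deterministically decayed variant; this
keeps the reference-anchored projection clean for the DE set — a block
substitution absent from the alignment anchor would otherwise be
scattered into spurious indels — while guaranteeing the motif is
recoverable from the DE consensus only.

What the generator does *not* emulate: real Alu subfamily phylogeny and
age structure, mappability artifacts of multi-mapping short reads,
batch and library-composition effects beyond a single size factor,
spatial gel artifacts, or missing-not-at-random phenotype data. Passing
recovery tests therefore demonstrates correctness of the estimators
under the stated statistical model, not robustness to those real-data
complications.

Recovery of the planted COBRA methylation level is assessed at the
group level: the generator plants *group* pattern probabilities, so the
recovered quantity is the group mean of duplicate-averaged sample
estimates, required to fall within ±2 percentage points. At the level
of a single gel measurement the 5% per-band noise alone propagates to a
%mC standard error of roughly 1.5 points, so a ±2-point criterion is a
statement about the group estimate, not about individual lanes.

## Problem sizes and runtime

The shipped tests run the screens at 21 + 21 samples with up to 1000
features, the sequence analyses at 500 sequences × 130 bp (100 seeds
for window recovery), COBRA recovery over 200 seeds, and oracle
comparisons over 1000 random vectors — sizes chosen so the whole suite
and the acceptance script each complete in a few minutes on a single
CPU while keeping every Monte-Carlo margin comfortable.

## Known limitations

Differential-expression calling is consumed, not computed: the package
filters supplied DE tables at adjusted p < 0.01 and |log2FC| > 1 but
contains no negative-binomial model or unwanted-variation removal.
The alignment projection drops insertions relative to the reference.
The conserved-region parameters (`delta`, `min_run`) are package
choices, not field constants, and should be reported alongside any
result. Correlation screens are association, not causal, statements;
with 21 + 21 samples, group-wise correlations have wide sampling
variability, which is why the per-group BH families are kept separate
and the per-cell n is always reported.
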