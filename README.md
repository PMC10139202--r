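# alureg

Transposable-element (TE) expression, DNA methylation and regulatory
association analysis for case/control brain transcriptome studies, with
a fully seeded synthetic-data generator so that every stage is testable
without restricted primary data.

## The problem

Alu elements — ~300 bp primate SINE retrotransposons whose left-arm
monomer carries the RNA Pol III A/B-box promoter — can rewire host gene
expression by acting as alternative promoters or enhancers, and their
activity is restrained epigenetically, largely by CpG methylation.
Studies of neurodevelopmental disorders therefore ask three linked
questions about a set of differentially expressed TEs (DETEs):

1. **Where are they?** Each TE locus is classified against RefSeq-style
   gene models into five disjoint feature classes: `exon`, `intron`, and
   the upstream annuli `up1k` (0–1 kb], `up10k` (1–10 kb] and `up50k`
   (10–50 kb] from the TSS, strand-aware. Because the annuli are
   disjoint shells, per-class position counts add up to the total.
2. **Do they move their neighbours?** *Cis*-regulation: Pearson
   correlation r between the normalized expression of a TE locus and
   each gene it is assigned to, computed for all samples, controls only
   and cases only, with Benjamini–Hochberg control applied separately
   within each of the three families (significance at adjusted p <
   0.05). *Trans*-regulation: the same screen over every DETE × DEG
   pair, followed by overlap algebra on the TE elements significant in
   each group (shared, case-only, control-only). Gene-panel enrichment
   uses the upper-tail hypergeometric probability P(X ≥ k).
3. **Is the epigenetic mark moving too?** The conserved promoter arm of
   DE elements is profiled against a size-matched non-DE set by
   reference-anchored alignment (consensus base and conservation = modal
   column frequency), and scanned with JASPAR-format matrices using the
   relative score (s − s_min)/(s_max − s_min) ≥ 0.8. Global methylation
   comes from COBRA gel band intensities A–F:

   %mC = 100·(E + B)/(2A + E + B + C + D), and the two-CpG patterns
   %mCmC = 100·F/(A+C+D+F), %uCmC = 100·C/(A+C+D+F),
   %mCuC = 100·D/(A+C+D+F), %uCuC = 100·A/(A+C+D+F),
   which close to 100 by construction. qPCR quantities use
   2^−ΔΔCt, and molecular measures are correlated against clinical
   scores (ADI-R domains) and neuron density with pairwise-complete
   Pearson r.

Every stage takes a data frame and returns a tibble, so analyses chain
with the pipe; fitted results have `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` figures.

## Worked example

```r
library(alureg)
library(tibble)

# COBRA: gel bands -> methylation level and patterns
bands <- tibble(sample_id = "brain01", assay_id = "AluSx_global",
                replicate = 1, A = 10, B = 20, C = 30, D = 40, E = 50, F = 60)
cobra_percentages(bands)[, c("sample_id", "pct_mC", "pct_mCmC",
                             "pct_uCmC", "pct_mCuC", "pct_uCuC")]
#> # A tibble: 1 × 6
#>   sample_id pct_mC pct_mCmC pct_uCmC pct_mCuC pct_uCuC
#>   <chr>      <dbl>    <dbl>    <dbl>    <dbl>    <dbl>
#> 1 brain01     43.8     42.9     21.4     28.6     7.14

# cis screen on synthetic data with 50 planted pairs among 1000
cfg <- synth_config(seed = 1)          # 21 + 21 samples, coupling r = 0.8
sim <- gen_counts(cfg)
cis <- cis_correlate(normalize_log(sim$te_counts),
                     normalize_log(sim$gene_counts),
                     sim$truth, sim$samples)
glance(cis)
#> # A tibble: 1 × 8
#>   mode    fdr n_pairs n_sig_all n_sig_ctrl n_sig_case n_te_sig_case ...
#> 1 cis    0.05    1000        54         49         50            50
```

54 of the 1000 tested pairs are significant across all samples: all 50
planted pairs (sensitivity 1.0) plus 4 false discoveries (observed FDR
0.074, within the nominal 0.05 family-wise target's expected range).
`tidy(cis)` returns the full per-pair record table (r, p, adjusted p and
significance per group), and `autoplot(cis)` plots control vs case r.

The whole pipeline — feature mapping, cis/trans correlation, consensus
and motif analysis, COBRA statistics, ΔΔCt folds, phenotype
association — runs from one config:

```r
cfg <- run_config(input_dir = "synthetic", out_dir = "results",
                  seed = 1, simulate = TRUE)
run_pipeline(cfg)   # writes stage TSVs plus a JSON manifest
```

A thin command-line wrapper with the same stages lives at
`inst/cli/alureg.R`.

## JASPAR matrices

Scanning consensus sequences against real JASPAR CORE matrices needs
the matrix text files on disk. Fetch them once on a networked machine:

```r
table3 <- readr::read_tsv(system.file("extdata", "table3_hits.tsv",
                                      package = "alureg"))
jaspar_fetch(unique(table3$matrix_id),
             "inst/extdata/jaspar/table3_matrices.jaspar")
```

The package does not redistribute JASPAR data; without the file the
TFBS-score acceptance check reports failure.

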