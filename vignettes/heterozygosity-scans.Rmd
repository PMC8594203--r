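---
title: "Heterozygosity-aware population genomic scans: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterozygosity-aware population genomic scans: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hetscan` analyses variation in heterozygosity across a diploid SNP panel
split into a wild progenitor group and a cultivar group (landraces plus
breeding lines). This vignette records the statistical models, the
parameters that matter, the design choices made where several reasonable
options existed, and what the bundled simulator does and does not emulate.

## The statistics

All statistics work from unphased dosage codes (0/1/2, `NA` missing); phase
is ignored throughout, and every estimator uses per-site complete
observations, so the effective sample size varies by site and no imputation
is performed.

**Expected heterozygosity.** At a biallelic site with alternate-allele
frequency $p$ among the $n$ non-missing allele copies,
$He = 1 - p^2 - (1-p)^2 = 2p(1-p) \in [0, 0.5]$, maximal at $p = 0.5$.
Window He is the unweighted mean over the window's SNPs.

**Observed heterozygosity rate.** For one accession,
het SNP calls / window span × 100 (% per bp). Terminal windows truncated at
a chromosome end are normalised by their actual span rather than dropped;
dropping them would bias chromosome-end regions.

**Nucleotide diversity.** Per site, the unbiased mean pairwise difference
among allele copies, $\pi_s = 2j(n-j)/(n(n-1))$ with $j$ alternate copies;
window $\pi$ is the site sum divided by the window span (per bp). Sites
with fewer than two called allele copies are skipped.

**Tajima's D.** The standard normalised difference between the
pairwise-diversity and segregating-sites estimators, with the published
constants evaluated at $n$ = the modal non-missing chromosome count across
the window's sites (a single $n$ is required by the constants; the mode is
the least-distorting summary under scattered missingness). The diversity
term is the window *sum* of $\pi_s$, not the per-bp value. Windows with
fewer than `min_segsites` (default 3) segregating sites return `NA`:
the variance term is unstable there.

**FST.** Default is Hudson's estimator as a *ratio of averages* across
sites, $\sum_s N_s / \sum_s D_s$ with
$N_s = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1}$
and $D_s = p_1(1-p_2) + p_2(1-p_1)$. Ratio-of-averages is robust for
window scans, where averaging per-site ratios explodes on low-diversity
windows. Nei's GST is available as an option. Slightly negative values are
legitimate sampling outcomes of the unbiased numerator and are reported
unclamped.

**p-distance.** For unphased diploid data the package defines the distance
between two samples as the mean over shared called sites of
$|g_i - g_j|/2$ (normalised dosage distance: 0 for identical genotypes, 1
for opposite homozygotes), averaged over all cross-group pairs. Pairs with
no shared called site are skipped with a warning.

**LD.** $r^2$ is the squared Pearson correlation of dosages over
pairwise-complete samples. `ld_decay()` scores all intra-chromosome pairs
up to 1 Mb (a seeded uniform subsample above $10^6$ pairs), averages per
1-kb bin, and reports the first bin whose mean drops to 0.2.

## Region calling

**SNP filter.** Sites are kept when MAF > 0.05 *and* integrity (per-site
call rate) > 0.8, both strict inequalities and both parameters.

**Het/hom partition.** Sliding 25-kb/5-kb windows on a single reference
accession; a window is homozygous when its het-SNP rate (fraction of window
bases) is below 0.002, heterozygous otherwise. Because the windows overlap,
labels conflict at overlaps; the package resolves them by *heterozygous
union*: a base is heterozygous if any overlapping window is, and the
homozygous class is the homozygous-window union minus that het union. The
union of the rarer label preserves the het signal that the analysis is
about. Merged regions with span ≤ 50 kb are discarded. Diversity between
the classes is compared with Welch (unequal-variance) two-tailed t-tests on
window-level values, per chromosome and genome-wide; Welch rather than
pooled because window counts and variances differ strongly between classes.
Statistic windows are assigned to a region class by their midpoint —
unambiguous and free of double counting. Per-chromosome t-tests are
reported raw (no multiplicity correction), matching how such per-chromosome
contrasts are conventionally displayed; the block-level trait segregation
tests do carry Benjamini–Hochberg q-values as an extra column.

**Heterozygous blocks.** Non-overlapping 20-kb windows; the block cutoff is
the population mean het-SNP count per (accession, window) pair, always
computed from the data at hand — on the study scale that mean happens to be
a two-digit SNP count, but it is a data property, not a constant. A window
is a block for an accession when its count is strictly above the cutoff.
Population block frequency per window is ranked, and windows at or above
the empirical 0.95 quantile (type-7, linear interpolation) become highly
heterozygous blocks; with heavy ties the marked set saturates, which is the
documented degenerate behaviour of an empirical quantile and exactly what
makes a handful of frequency-1.0 blocks separable from a continuous
background. Trait segregation per block uses the two-sided Wilcoxon
rank-sum test: exact enumeration when both groups have ≤ 10 untied values,
otherwise the tie-corrected normal approximation without continuity
correction. Accessions count as heterozygous for a block when any
constituent window carries their block call (the per-block grouping; a
genome-wide grouping would mix signals across blocks).

**Sweep scans.** 50-kb/10-kb windows; per window the He or π
wild/cultivar ratio, so large values mean diversity lost in cultivars.
Windows with fewer than `min_sites` = 5 SNPs or zero cultivar diversity are
excluded from the quantile rather than given ratio 0 or ∞ — sparse windows
produce unstable ratios, and an optional flag can instead force
zero-denominator windows above threshold. The threshold is the empirical
top-1 % quantile of defined ratios by default; printed thresholds from any
particular dataset are outputs, never constants. Above-threshold windows
that overlap or book-end merge into sweeps; the He and π sweep sets are
intersected for the joint calls. The 14-vs-374 style sample-size imbalance
is handled by the frequency-based estimators themselves; an optional seeded
down-sampling of cultivars mirrors the common matched-size device for FST.

## The simulator and the validation design

`simulate_genotypes()` is a forward allele-frequency simulator, not a
coalescent: the scans consume site-frequency and heterozygosity structure
only, so linkage realism beyond block-level correlation is unnecessary (LD
functions are exercised by explicit block-copied genotypes in the tests).
Wild allele frequencies are Beta(0.8, 0.8) — a U-shaped spectrum with mean
0.5; wild genotypes are Hardy–Weinberg. Cultivar frequencies drift around
the wild values (Beta with variance $c\,p(1-p)$, $c = 0.05$), and cultivar
genotypes are drawn with heterozygote probability $2p'(1-p')(1-F)$ with
$F = -0.1$, a minimal parameterisation of the genome-wide heterozygote
excess of a clonally propagated crop (an explicit clonal pedigree would add
parameters without changing the statistics the scans consume). Planted
sweeps set the cultivar frequency to 0.98; planted balancing blocks set the
heterozygote probability to 0.9. Missing calls are dropped uniformly at
2 %. A single RNG stream from one seed makes every output byte-identical
under the same configuration.

The default scenario is desk-scale: 2 chromosomes × 5 Mb, 1 SNP / 500 bp
(comparable to a dense crop resequencing map), 14 wild + 200 cultivars,
five 100-kb sweeps and three 60-kb balancing blocks. Two sizing choices
deserve a note:

* **Sweep length 100 kb** is the scale of empirically merged sweep regions
  in dense crop panels (tens of kb to ~100 kb). With 50-kb/10-kb windows a
  100-kb sweep contains six fully-inside windows.
* **Recovery validation runs the scans at `top_q = 0.03`**, the fraction of
  windows fully inside planted sweeps
  ($5 \times (100 - 50 + 10)\,\text{kb} / 10\,\text{Mb}$). A recovery
  experiment is only informative when the scan's marked-window budget
  matches the planted signal: a top-1 % scan on this genome can mark ~10
  windows, and asking it to re-cover 30 planted windows measures the
  budget, not the method. The pipeline default stays at the conventional
  top 1 %; the calibrated value is a property of the validation design,
  not a tuned constant — the affected-window ratios (≈ 5–8) are separated
  from the background (≈ 1) by a wide gap, so any budget between the
  planted fraction and that gap yields the same calls.
* **Balancing blocks are 60 kb** so that a planted block's heterozygous
  window union always exceeds the 50-kb minimum region length of the
  het/hom partition; a 20-kb block is recoverable by the block-frequency
  analysis but sits knife-edge against that length filter.
* **Region-partition threshold on simulated data.** The 0.002 rate
  threshold presumes the very dense variant set of a reference accession
  mapped to itself (heterozygosity of order 0.7 %, i.e. a het site every
  ~150 bp). At the simulator's population-map density (1 SNP / 500 bp)
  even a fully heterozygous window cannot reach 0.002, so validation runs
  use 0.001 — the midpoint between the simulated background rate (~0.0007)
  and the planted-block rate (~0.0016), derived from those densities
  before any recovery experiment. The pipeline default remains 0.002.

What passing these tests shows — and what it does not: the simulator
reproduces the *frequency structure* the method assumes (heterozygote
excess, sweeps as near-fixation, balancing blocks as forced
heterozygosity). It has no recombination map, no mutation-rate
heterogeneity, no clonal pedigree and no realistic haplotype LD, so
recovery on it validates the statistics, window logic, thresholds and
merging — not robustness to linked-selection confounding or to genotyping
error structure in real resequencing data.

## Numerical conventions

Coordinates are 0-based half-open internally; VCF I/O converts to 1-based,
BED is written natively 0-based. Quantiles are type 7 (linear
interpolation); scan marking uses ≥ the threshold, the block cutoff uses
strict >. Indels and multiallelic records are excluded on read, with a
count. Mood's median test assigns ties at the grand median to the
"≤ median" cell; pairwise median tests are Bonferroni-adjusted by default
(Benjamini–Hochberg optional) and compact letters are assigned greedily in
descending-median order, so two classes share a letter exactly when their
adjusted pairwise difference is not significant. Degenerate inputs follow
the conventions documented on each function: empty windows give `NA`,
monomorphic windows give $\pi = 0$, constant-value t-tests give $p = 1$
when means agree.

## Problem sizes used in the shipped validation

The test-suite and acceptance-script runs use the default scenario above
(20 seeds for each recovery experiment), a 400-kb single-chromosome cohort
with 200 cultivars for the balancing-block experiment, 1,000 random small
instances per statistic for the oracle comparisons, and 1,000 replicates
for the type-I-error calibration of the trait tests. These sizes give
stable estimates (binomial standard error ≈ 0.7 % on a 5 % error rate at
n = 1000) while keeping a full run in minutes on one CPU.

## Known limitations

Phase-aware statistics (haplotype sweeps, iHS/XP-EHH) are out of scope, as
are variant calling, imputation and mixed-model association scans; the
association module consumes externally nominated candidate SNPs. The
p-distance definition above is one of several possible codings for diploid
data and is not comparable to haploid-sequence p-distances. FST estimates
between very small groups carry the usual negative-bias wobble of the
unbiased numerator.
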