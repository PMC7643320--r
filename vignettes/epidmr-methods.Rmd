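---
title: "Methods: window-based DMR analysis for MeDIP-seq counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-based DMR analysis for MeDIP-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidmr)
```

## Scope and model

`epidmr` analyzes MeDIP-seq read counts over non-overlapping 1 kb genomic
windows to find differential DNA methylation regions (DMRs) between a
diseased and a non-diseased group of animals, and characterizes those DMRs
as candidate biomarkers. The pipeline starts from aligned read positions or
a precomputed window-by-sample count matrix; read QC, trimming and
alignment are upstream of its scope, as are live annotation-database
queries (gene association is computed against a user-supplied annotation
table) and pathway enrichment beyond counting against a supplied mapping.

The count model is the standard negative binomial for sequencing data:
window $w$ in sample $s$ has

$$y_{ws} \sim \mathrm{NB}(\mu_{ws}, \phi), \qquad
  \mathrm{Var}(y_{ws}) = \mu_{ws} + \phi\,\mu_{ws}^2,$$

with a single common dispersion $\phi \ge 0$ shared by all windows
($\phi = 0$ is the Poisson limit). A common dispersion, rather than a
tagwise or trended one, matches the small group sizes this design
anticipates: with 8 or fewer animals per group, per-window dispersions are
too noisy to estimate, while genome-wide pooling over tens of thousands of
windows pins the common value tightly (the tests show recovery of a
simulated $\phi = 0.2$ within about 5% at 10,000 windows).

## Normalization

Between-sample scaling uses a trimmed mean of M-values (TMM) computed on
raw counts: for each sample against a reference (the sample whose
upper-quartile count is closest to the mean upper quartile), windows with a
zero in either sample are dropped, the most extreme 30% of M-values
(log2 ratios) and 5% of A-values (average log2 abundance) are trimmed, and
the factor is the anti-log of the trimmed mean M; factors are normalized to
geometric mean one. Because the M-values are not first adjusted by library
size, the factors absorb sequencing-depth differences together with
composition bias: duplicating a sample's reads doubles its factor. The
effective library size used for count equalization is therefore the
geometric-mean raw library size times the factor — for a pure depth
difference this reduces exactly to the raw library sizes, and the factor
ratio, not the raw-size ratio, carries the correction when composition
bias is present. A `total-count` mode is available that ignores TMM and
uses raw library sizes unchanged.

## The per-window exact test

For one window, counts are scaled to a common library size (the geometric
mean of the effective sizes) and rounded to integers — nearest integer,
ties to even, because the conditional law below needs integer sums — and
group sums $S_A$, $S_B$ are formed. With equalized libraries,
$S_A \sim \mathrm{NB}(n_A\hat\mu, \phi/n_A)$ and
$S_B \sim \mathrm{NB}(n_B\hat\mu, \phi/n_B)$ under the null, where
$\hat\mu = (S_A+S_B)/(n_A+n_B)$. Conditional on the total $S = S_A + S_B$,
the two-sided p-value is the summed probability of every value of $S_A$ no
more likely than the observed one (the minimum-likelihood rule). The
conditional distribution is enumerated exactly over $0..S$; since it
depends only on $S$ (given $n_A$, $n_B$, $\phi$), the genome-wide scan
computes it once per distinct total, which keeps 20,000 windows under a
few seconds. Floating-point ties are absorbed by a $1+10^{-12}$ relative
tolerance on the "no more likely" comparison. The exactness of the
enumeration is pinned against an independent brute-force oracle on all
totals up to 30, and the Poisson-limit case (10 vs 0 reads, equal sizes)
returns the binomial closed form $2/1024$.

The log2 fold change is
$\log_2\!\big((S_A/n_A + 0.5)/(S_B/n_B + 0.5)\big)$; the 0.5 pseudo-count
per group mean keeps zero-count windows finite. Windows with mean raw
count below a configurable floor (default 1 read/window) are marked
untested and carry $p = 1$; FDR (Benjamini–Hochberg step-up) is computed
over tested windows only, so the multiplicity burden reflects windows that
could in principle reject. Whether the test is distributionally honest is
the contract — numerical agreement with any particular count-model package
is not — and the null simulations verify a rejection fraction at
$p < 0.05$ of about 0.049 (the mild conservatism comes from the
discreteness of the conditional law at finite counts).

## Seed-and-extend DMR assembly

Windows with $p$ strictly below the seed threshold (default $10^{-4}$;
ties at the printed threshold are excluded by convention) initiate one
region per maximal run of adjacent seeds. Regions then grow to a fixed
point: any tested window with $p < 0.1$ whose whole span lies within
1000 bp of a region's current edge is absorbed and extends the edge, and
regions that come to touch or overlap merge. On a 1 kb grid with the
default reach this means exactly the adjacent window qualifies, so a
single intervening window with $p \ge 0.1$ blocks extension — the
strictest reading of the extension rule, and the one consistent with the
hand-traceable cases (a `[seed, 0.05, seed]` triple merges into one
3 kb DMR; `[seed, 0.5, seed]` stays two 1 kb DMRs). Untested
(low-coverage) windows behave as $p = 1$ and block extension. Absorbed
extension windows widen the reported interval but do not count toward
`n_significant_windows`, which tallies member windows at the seed
threshold; DMRs with at least two such windows form the "multiple-window"
column of the threshold sweep. After assembly, an audit scan confirms no
absorbable window remains adjacent to any DMR edge.

Each DMR is summarized by its minimum member p-value, the member log2 FC
of largest magnitude with its sign preserved (so a DMR mixing +1.5 and
−2.2 reports −2.2), the summed member CpG count, and CpG density per
100 bp. The methylation direction is the sign of that fold change, and the
hypermethylated fraction is reported over directed DMRs.

## Genomic context and comparisons

CpG density histograms bin by `floor(density)`; length histograms bin by
`ceiling(length/1 kb)`. Chromosomal clusters are maximal runs of at least
3 DMRs with consecutive gaps at most 2 Mb — an operationalization of
visual clustering on chromosome plots, configurable and not claimed to
reproduce any particular study's boxes. Gene association uses a minimum
genomic distance between DMR and gene body of at most 10 kb, inclusive at
the boundary (0 = overlap); the distance rule is a documented assumption,
as annotation-based association criteria vary between studies. Functional
categories use a single-category-per-gene mapping table; a gene associated
with several DMRs in one set counts once, and unmapped genes count as
"unknown".

Cross-disease comparisons treat DMR sets as interval sets: two DMRs
overlap when they share at least one bp (half-open coordinates; an
optional minimum-overlap fraction tightens this). Venn region counts are
reported per set because sets have different cardinalities — a shared
"element" is an overlap relation, not a merged interval. The extended
overlap compares a strict set (seed threshold) against another disease's
relaxed set (assembled at $p < 0.05$); comparing a set against its own
relaxed assembly gives 100% by construction, the expected diagonal.
The PCA of RPKM depths at DMR windows treats samples as observations with
window features centered but not scaled (RPKM is already
depth-normalized; unit-variance scaling is available by flag), and fixes
each component's sign by forcing its largest-magnitude loading positive.
Group separation is summarized by the mean silhouette of disease labels on
(PC1, PC2).

## The pathology arm

Histopathology classification follows the standard blinded-observer
protocol: per-image abnormality counts are converted to densities per mm²,
a tissue-specific cutoff is the control-group mean plus two standard
deviations (the sample, $n-1$, estimator — the conventional choice for a
control sample), and a tissue is finally called diseased when at least two
of the available observers (two, or three when the first two disagree)
exceed the cutoff. The two-SD rule is applied to the summed abnormality
density per tissue by default, with a per-type option, since protocols
differ on this point. Disease tables of `+`/`-`/`n/a` flags are parsed
with missing entries excluded from denominators; the per-animal total
counts present flags among the six primary pathologies, and multiple
disease is a derived flag for totals of at least two — a derivation
consistent with every row of the bundled 41-animal table, whose totals
row (e.g. testis 14/40 = 35%, multiple disease 12/41 = 29%) the package
reproduces exactly, with percentages rounded half-up to match the printed
style. Incidence comparisons use the two-sided Fisher's exact test
(minimum-likelihood rule, via `stats::fisher.test`), cross-checked in the
tests against a full hypergeometric enumeration.

## The synthetic-data generator

The generator emulates the statistical structure the window tests assume:
non-overlapping windows with Poisson-distributed CpG counts around a
configurable rate, lognormal per-sample depth factors, NB counts at a
baseline mean, and planted multi-window epimutations applying a
$2^{\pm\delta}$ factor to diseased samples. Planted regions are
grid-aligned, non-overlapping, and split exactly half hyper-, half
hypomethylated (rounded down, randomly assigned), emulating the roughly
even split of methylation gains and losses reported among
disease-associated sperm DMRs. All randomness derives from the single
config seed through fixed per-stage sub-streams, so identical configs give
bit-identical outputs.

Defaults describe the desk-scale study conditions used throughout the
tests: 2 chromosomes × 10,000 windows of 1000 bp, 8 diseased vs 8
non-diseased samples, baseline 50 reads/window (≈1 M reads per sample over
20 Mb — a scaled-down proxy for the 10–20 M reads per pool typical of
MeDIP-seq libraries), dispersion $\phi = 0.1$, depth-factor sd 0.1 on the
log scale, and 20 planted 3-window DMRs at $|\log_2 FC| = 2$. Real
sequencing depths and dispersions are study-specific and the originating
data report neither, so these are free parameters chosen once as realistic
for pooled MeDIP-seq, and documented as such. What the generator does
*not* model: read-level artifacts (FASTQ simulation), MeDIP CpG-affinity
and fragment-size enrichment bias, alignment error, and correlated
biological covariates. Passing tests therefore demonstrate that the
statistics and the assembly logic behave as specified under the assumed
count model — not that any particular biological study's DMR counts would
be reproduced, which would require the raw sequencing data.

## Numerical and design choices

* Coordinates are 0-based, half-open everywhere in memory and on disk
  (BED-compatible); 1-based closed coordinates appear only inside
  GenomicRanges internals.
* Reads are assigned to windows by midpoint, with a boundary midpoint
  belonging to the right-hand window; this assigns each read exactly once.
* Library equalization rounds ties to even; an all-zero window returns
  $p = 1$.
* Strict inequalities at both DMR thresholds; assembly is iterated to a
  fixed point and the result is order-deterministic.
* Degenerate inputs fail loudly: zero section areas, fewer than two
  control densities, all-zero count columns, unsorted or overlapping
  interval sets, unknown disease-table symbols (reported with row and
  column), and p-values outside $[0,1]$ all raise errors naming the
  offender.
* Sweep thresholds must be sorted descending; DMR counts are
  non-increasing as the threshold tightens because any seed lost to a
  tighter threshold ($p < 10^{-2}$) remains an extension window
  ($p < 0.1$) and keeps chained regions merged.

## Problem sizes

The bundled tests and the acceptance script run the simulator at up to
2 × 10,000 windows with 16 samples (five null replicates plus one planted
run), sizes chosen so the full suite completes in well under a minute of
compute while leaving Monte-Carlo standard errors far smaller than every
tolerance asserted. The same code paths scale linearly in windows ×
samples; the per-total memoization of the conditional law keeps the exact
test's cost sublinear in practice.

## Known limitations

* The common-dispersion, exact-test formulation deliberately omits GLM
  covariates, paired designs, and tagwise/trended dispersion.
* The extension rule's bp-reach semantics are defined on the window grid;
  exotic grids (reach much larger than the window) absorb windows across
  unabsorbed gaps by design.
* Venn counts for more than four sets are unsupported.
* The histopathology arm ingests qualitative flags (obesity, late
  puberty, tumor) as given; only tissue pathologies are computed from
  abnormality densities.
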