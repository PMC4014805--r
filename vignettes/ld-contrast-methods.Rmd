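---
title: "Methods: between-population LD contrast scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: between-population LD contrast scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varldscan)
```

## The model and its assumptions

A recent selective sweep drives one haplotype (and its neighbours) toward
high frequency, so the swept region carries few distinct haplotypes and an
unusually coherent local LD structure. When two populations diverged under
different selection pressures, the *organization* of LD in such a region
differs between them even where allele frequencies are similar. `varldscan`
quantifies this by sliding a window of `w` consecutive SNPs along each
chromosome and, per population, forming the `w x w` matrix of signed
r-squared values,

$$M_{ij} = \operatorname{sign}(r_{ij})\, r_{ij}^2 ,\qquad M_{ii}=1,$$

with $r_{ij}$ the Pearson correlation of unphased dosages over
pairwise-complete samples (composite LD — no phasing is assumed anywhere).
The window score is the $\ell_1$ distance between the descending-ranked
eigenvalue spectra of the two populations' matrices:

$$S \;=\; \sum_{k=1}^{w} \bigl|\lambda^{(A)}_{(k)} - \lambda^{(B)}_{(k)}\bigr|.$$

Both matrices have unit diagonal, hence equal trace $w$; a plain difference
of traces would be identically zero, so the absolute form is the only
reading under which the score's magnitude measures dissimilarity, and it is
what makes $S$ a true metric on ranked spectra (symmetric, nonnegative, zero
iff the spectra coincide, triangle inequality from the $\ell_1$ norm). The
eigenvalue spectrum captures how correlation mass is organized — one
dominant block versus diffuse small correlations — while being invariant to
SNP sign conventions, which is why the *ranked-spectrum* comparison is
insensitive to allele-coding flips that merely permute sign patterns.

Assumptions worth stating: (i) markers are biallelic, autosomal and
polymorphic in both populations — monomorphic SNPs carry no LD information
and are rejected with an explicit error rather than silently patched;
(ii) samples within a population are unrelated after QC (duplicates inflate
LD coherence); (iii) dosage coding is harmonized between populations
(`intersect_common_snps()` recodes swapped alleles as `2 - d` and drops
markers whose allele sets differ beyond a swap).

## Scores, standardization and calling

Raw scores depend on window span in bp and on background LD, both of which
differ between comparisons. Scores are therefore standardized genome-wide
*within a comparison* — $S' = (S - \bar S)/\mathrm{sd}(S)$, sample standard
deviation ($n-1$) — giving each comparison mean 0 and sd 1. Windows with
$S'$ at or above the empirical 99.9th / 99.99th percentile (linear
interpolation between order statistics, `stats::quantile()` type 7, fixed
for determinism) are flagged; flagged windows whose SNP-index ranges overlap
or abut merge into one signal region. A region inherits its boundaries from
the mid-bp (arithmetic mean of first and last SNP position; insensitive to
uneven spacing, unlike the median SNP) of its first and last windows. A
contiguous super-threshold run thus becomes exactly one signal, which is the
merge rule consistent with defining region boundaries by the first and last
window of a run.

Monte-Carlo significance: `permutation_null()` pools the individuals,
reassigns them into two groups of the original sizes `n_perm` times, and
reports per-window $p = (1 + \#\{S_{perm} \ge S_{obs}\})/(n_{perm}+1)$.
Within permuted groups a marker can go monomorphic by chance; those
correlations contribute 0 rather than erroring, since the permutation scheme
itself guarantees the observed data passed the polymorphism check.

## Quality control

Per population, in this order: sample call rate $\ge$ 0.90, SNP call rate
$\ge$ 0.90, minor allele frequency $\ge$ 0.05, Hardy–Weinberg 1-df
goodness-of-fit $p > 10^{-6}$ (the squared z-test; the exact test is out of
scope), then relatedness pruning on the frequency-weighted genomic kinship
$K_{ij} = \overline{(g_i-2p)(g_j-2p)/(2p(1-p))}$, greedily removing from any
pair with $K > 0.8$ the member with the lower call rate (ties: the
lexicographically later id, so the better-genotyped individual always
survives and the outcome is deterministic). Because sample removal shifts
per-SNP statistics, the pass repeats until a fixed point; the report
attributes each removal to the first filter that caught it. Kinship from
sample-estimated frequencies is biased low by $O(1/n)$ — with 40–100
samples a true duplicate scores roughly 0.93–0.97 rather than 1.0, still far
above the 0.8 cutoff.

## Population structure view

`classical_mds()` converts kinship to squared Euclidean distances
($D^2_{ij} = K_{ii} + K_{jj} - 2K_{ij}$, negatives clipped to 0 with a
warning) and embeds them by Torgerson scaling via `stats::cmdscale()`.
Negative eigenvalues (non-Euclidean kinship noise) are dropped from the
coordinates and from the explained-variance denominator; eigenvalues within
a $10^{-8}$ relative tolerance of zero are treated as degenerate and their
columns zeroed. Each coordinate column is sign-fixed so its
largest-magnitude entry is positive, making plots and tests reproducible.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `window_size` | 50 | SNPs | large enough for a stable spectrum, small enough to localize signals |
| `step` | 1 | SNPs | maximal positional resolution of the scan |
| percentiles | 99.9, 99.99 | % of windows | top 0.1% / 0.01% of the genome-wide score distribution |
| `maf_min` | 0.05 | frequency | standard dense-panel floor; also guarantees polymorphism for the scan |
| call-rate minima | 0.90 | fraction | per SNP and per sample |
| `hwe_p_min` | 1e-6 | p-value | removes gross genotyping artefacts only |
| `ibs_max` | 0.8 | kinship | duplicates/clones; half-sibs stay |
| `windowed_mean_r2` | 200 kb / 20 kb / 50 SNPs | — | regional LD profile used for breed assignment |
| `ld_decay` | 100 kb max, 10 kb bins | — | decay-curve comparison between populations |

## The simulator: what it emulates, and what it does not

`simulate_pair()` uses a founder haplotype mosaic: each population draws
`n_founders` (default 30) haplotypes at allele frequencies shared between
populations (uniform on `[maf_floor, 1 - maf_floor]`), and each sample
haplotype copies founders with a per-interval switch probability. Shared
frequencies with independently drawn founders give the two populations
correlated allele-frequency spectra but distinct LD patterns — the situation
the scan is designed for. The default switch probabilities (0.05 vs 0.10 per
~2-kb interval) make population 1 hold LD over roughly twice the distance of
population 2, reproducing qualitatively the slow- versus fast-decay contrast
seen between taurine and indicine cattle panels (mean r² ≈ 0.3 at ~40 kb vs
~20 kb). Defaults — 150 samples per population and 2 chromosomes × 5,000
markers at ~2 kb spacing (a 20-Mb genome) — keep a full scan in seconds on
one CPU while leaving the sweep a small fraction (~1.5%) of the genome.

A sweep is realized as *copying-pool collapse*: inside the sweep interval
the sweep population's founder pool shrinks to `residual_founders` (default
2), by mapping founder indices modulo the residual pool so mosaic continuity
is preserved. This collapses local haplotype diversity — the LD footprint of
a sweep — without the allele-frequency shift that frequency-based statistics
need, and `residual_founders >= 2` keeps markers polymorphic (markers where
the residual haplotypes agree go monomorphic and are legitimately lost to
the MAF filter, exactly as fixed SNPs are lost in real sweeps). Setting
`residual_founders = n_founders` makes the "sweep" a no-op, which the tests
use as a null-effect control. Because residual haplotypes still recombine,
regional r² is elevated but well below 1 — a realistic, detectable contrast
(the scan recovers the default 300-kb sweep at the 99.9th percentile in
essentially every seed) rather than a caricature.

Not emulated: demographic history (no drift trajectories, bottlenecks or
migration — copying is exchangeable within a population), ascertainment bias
of commercial chips, genotyping-error structure beyond uniform missingness,
and real recombination-map heterogeneity. Passing tests therefore show the
machinery is correct and well-calibrated on data with realistic LD
structure; they do not certify power on any particular real panel.

## Numerical choices and degenerate inputs

- Dosage counts the lexicographically later allele; deterministic without an
  external frequency reference. A marker observed with a single allele in a
  PED file is ambiguous on disk (the same limitation PLINK text has); it
  re-reads as dosage 0 with a placeholder partner allele.
- Pairwise correlations use pairwise-complete observations; inside the scan
  they are assembled exactly from blocked cross-products of the zero-filled
  dosage matrix and the observation indicator (BLAS), which matches
  `stats::cor()` to machine precision and keeps a 10,000-SNP scan under ten
  seconds.
- An undefined correlation (zero variance on the joint support) is `NA` at
  the API surface, contributes 0 inside window means, and is an explicit
  error inside `window_corr_matrix()` for a monomorphic column.
- Eigen-decomposition uses the symmetric (LAPACK `dsyev`) path with
  descending eigenvalues; scores need values only, not vectors.
- `standardize()` refuses constant raw tracks (degenerate), and
  `percentile_threshold()` refuses unstandardized tracks.
- Coordinates are 1-based inclusive everywhere in memory; BED files are
  converted from 0-based half-open on read and back on write. Interval
  overlap, union and coverage arithmetic delegate to
  `GenomicRanges`/`IRanges`.
- A/T and C/G allele swaps are treated as plain swaps (no strand flipping):
  simulated and single-platform data share strand. Cross-platform merging
  would need a strand-aware step that is deliberately out of scope.
- `mid_bp` uses `round()` on the two-position mean; ties-to-even on the
  half-bp is irrelevant at genomic scale but fixed, hence reproducible.

## Problem sizes used by the tests and acceptance script

Module tests run on datasets of 40–120 samples and 200–1,500 markers
(seconds each). The behavioural guarantees run at the package's standard
study conditions: standardization and window-count checks on scans of
~1,000–9,500 windows; sweep recovery over 20 seeds at the default
configuration with one 300-kb residual-2 sweep; null calibration on two
150-sample halves of one 5,000-SNP population with 29 permutations (p-value
resolution 1/30, thinned to ~one window per window-width before the
uniformity check because overlapping windows share SNPs). The acceptance
script repeats the recovery experiment over 10 seeds and reports rates plus
the analytic error bounds; everything derives from a single `--seed`.

## Known limitations

- The scan compares exactly two populations; multi-way contrasts are run as
  all pairwise comparisons (`run_comparisons()`), not as a joint score.
- Permutation p-values inherit the discreteness of `n_perm` and the strong
  positive correlation of overlapping windows; they are per-window, not
  family-wise.
- Kinship-based pruning approximates the published frequency-weighted
  estimator; its absolute scale near the 0.8 cutoff depends on the
  frequency weighting, so cutoffs tuned on other software transfer only
  approximately.
- Windows are defined in SNP-index space, so physical window span varies
  with local marker density; the genome-wide standardization absorbs the
  average effect but locally sparse regions are scanned at coarser
  resolution.
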