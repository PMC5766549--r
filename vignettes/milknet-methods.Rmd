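---
title: "Models and design choices in milknet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in milknet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

milknet chains six stages — synthetic-cohort generation, genotype I/O and
marker QC, mixed-model GWAS, gene-set enrichment, AWM construction, and
PCIT network inference — into one reproducible pipeline for correlated
dairy-composition traits. This vignette documents the statistical models,
the tunable parameters and their defaults, the numerical choices, and what
the synthetic data can and cannot tell you about behaviour on real cohorts.

## The polygenic model and its GRM

Each trait is analysed with the additive polygenic model
$y = X\beta + a + e$, $a \sim N(0, K\sigma_g^2)$,
$e \sim N(0, I\sigma_e^2)$. The fixed effects are herd-date contemporary
group, parity class (1, 2, 3, 4+) and 30-day days-in-milk class — class
factors without assumed magnitudes. The relationship matrix is the
identity-by-state estimator

$$f_{ij} = \frac{1}{N}\sum_k
  \frac{(x_{ik}-p_k)(x_{jk}-p_k)}{p_k(1-p_k)},$$

with genotypes on the half-count scale $x \in \{0, \tfrac12, 1\}$ and
$p_k$ the "+"-allele frequency computed from non-missing calls (missing
dosages are mean-imputed before centring). Under Hardy–Weinberg equilibrium
$E[(x-p)^2] = pq/2$, so the diagonal of this estimator sits near 0.5.
`build_grm()` returns the coefficients exactly on that scale; the mixed
model (`grm_eigen()`, `fit_polygenic()`) rescales the matrix to unit mean
diagonal so that $\sigma_g^2$ is the per-individual additive variance and
$h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$ is a genuine variance fraction.
Without that normalisation the heritability reported by the model and the
realized variance fraction of simulated genetic values cannot agree — the
two conventions differ by the mean diagonal, about a factor of two.

REML exploits the single-random-effect structure: after rotating $y$ and
$X$ by the eigenvectors of $K$, the restricted likelihood is profiled on
$h^2$ and maximised by Brent search on $[0, 0.999]$ (tolerance $10^{-9}$),
with both endpoints checked explicitly because boundary maxima at
$h^2 = 0$ are common for weakly heritable traits. Eigenvalues are floored
at zero, which guarantees a valid covariance even when the SNP set used
for the matrix is smaller than the cohort (as in the permutation test).
Collinear fixed-effect columns are dropped by QR pivoting with a warning.

## GRAMMAR, gamma recalibration and genomic control

The association scan regresses the BLUP residuals
$\hat e = y - X\hat\beta - \hat a$ on each SNP dosage by OLS, excluding
missing calls pairwise. Residual regression is deliberately cheap but
deflates both effect sizes and test statistics. With
$\Sigma = h^2K + (1-h^2)I$ the fitted correlation structure and
$\rho = \frac{1}{M}\sum_k (\tilde g_k'\Sigma^{-1}\tilde g_k)/
(\tilde g_k'\tilde g_k)$, two scalar corrections restore the intended
scales:

* effects: $E[\hat\beta_{GRAMMAR}] = (1-h^2)\rho\,\beta$, so $\beta$ is
  divided by $\gamma = (1-h^2)\rho$. On simulation with a 5%-variance QTL
  at $n = 500$ this brings the mean estimate back to within ~10% of truth;
  without the $(1-h^2)$ term the deflation is only half-corrected.
* statistics: the naive $\chi^2$ relates to the score test through
  $\gamma_{test} = n\rho/\mathrm{tr}(\Sigma^{-1})$; dividing restores a
  unit-median null. In a family-structured cohort the uncorrected scan has
  $\lambda \approx 0.85$, which genomic control alone would have to repair.

Genomic control is then applied on top:
$\lambda = \mathrm{median}(\chi^2)/0.4549$, and corrected P-values come
from $\chi^2/\lambda$. Because the residual scan is conservative rather
than inflated, $\lambda$ is used as estimated (values below 1 inflate the
statistics back); `gc_floor_lambda = TRUE` restores the
deflation-only convention. The SE column is derived as
$|\beta|/\sqrt{\chi^2_{GC}}$ so that $z = \beta/\mathrm{SE}$ equals the
GC-corrected signed statistic exactly — these $z$ values are what the AWM
stores. Per-SNP variance is $2pqa^2$ with $a$ the gamma-corrected effect,
reported as a percentage of $\sigma_g^2$ from the unconditional fit (the
denominator is configurable but defaults to unconditional, since the
conditional $\sigma_g^2$ is itself shrunken by the conditioning).

The conditional scan appends lead-SNP dosages (mean-imputed) to $X$,
refits, rescans, and reports the relative change in $\sigma_g^2$ and
$h^2$ — the signature of a major QTL is a large drop.

## Marker quality control

Markers are retained when call rate > 0.95, minor allele frequency
> 0.005 (computed from non-missing calls), and the exact Hardy–Weinberg
test (Wigginton-style enumeration, no mid-P) gives
$P > \alpha/m$ with $\alpha = 0.001$ and $m$ the pre-filter marker count
by default. Using the pre-filter count keeps the filter idempotent in
practice and matches the usual chip-QC convention; the divisor is
exposed (`hwe_m`) for users who prefer post-filter counting. Removal
reasons are reported per SNP in threshold order (call rate, MAF, HWE).

## Gene-set enrichment

SNPs with nominal $P < 0.05$ are assigned to every gene within 15 kb of
its ends (1-based inclusive intervals; a SNP exactly 15,000 bp away is
assigned). The gene universe is the set of genes with at least one
assigned SNP — not the whole annotation — because genes invisible to the
chip cannot enter either margin of the table. Categories are intersected
with the universe and kept when their size lies strictly between 10 and
1000; each retained category gets a one-sided Fisher exact
(hypergeometric upper-tail) P for over-representation and a
Benjamini–Hochberg q-value computed over exactly the retained list. BH is
the minimal-assumption reading of "q-value"; the output metadata records
the method. No gene-length bias correction is applied — the contract here
is the plain Fisher test.

## AWM selection and the permutation test

A SNP enters the association weight matrix when it is associated with the
key phenotype ($P \le 0.05$, inclusive) **or** with at least three other
traits ($P < 0.05$, strict), and lies strictly closer than 10 kb to its
nearest annotated gene. The OR combination follows the original AWM
recipe, in which key-trait association and multi-trait association are
alternative entry routes; a toggle (`rule = "and"`) gives the sequential
reading. One SNP represents each gene: smallest key-trait P, ties broken
by larger $|z|$ on the key trait, then lowest genomic position — a total
order, so the matrix is independent of input row order. Cells hold the
GC-standardized $z$ for every trait; the rare missing fit becomes 0 with
the position recorded in a mask rather than dropping the row. Ap is the
mean number of other traits associated at $P \le 0.05$ among
key-associated SNPs.

Trait structure is summarised by average-linkage hierarchical clustering
on $1 - r$ of AWM columns (the linkage is configurable; average is the
conventional choice for correlation screens).

The permutation test asks whether the AWM SNPs capture more phenotypic
variance than random SNP sets of the same size: the statistic is
$\sigma_g^2/(\sigma_g^2+\sigma_e^2)$ from a REML fit whose relationship
matrix uses only the candidate set, and the null resamples equally sized
sets without replacement ($(1 + \#\{null \ge obs\})/(R+1)$, reported as
"< 1/(R+1)" when the observed value tops every replicate). Random sets
exclude the observed SNPs by default for a cleaner null; the calibration
property is exactness under exchangeability, which holds when the
candidate set is itself a random draw. For a pure-noise trait the
statistic collapses onto the $h^2 = 0$ boundary for about half the
repeats, so its empirical P is discrete there by construction — a
property of the statistic, not of the implementation.

## PCIT and the TF trio

For every unordered gene trio $(x, y, z)$ the three first-order partial
correlations are computed, the tolerance $\varepsilon$ is the mean of the
absolute partial/direct ratios (terms with $|r| < 10^{-12}$ skipped,
denominators clamped at $10^{-12}$), and edge $(x,y)$ is locally
non-significant when $|r_{xy}| < |\varepsilon r_{xz}|$ **and**
$|r_{xy}| < |\varepsilon r_{yz}|$. One failing trio kills an edge. The
conjunctive rule is the published PCIT contract; note its consequence,
verified in the tests: a weak edge flanked by two strong ones survives a
single trio (it fails only one comparison) and is instead removed by the
$|r| \ge 0.80$ magnitude filter that follows. Networks are built from
edges that are both PCIT-significant and above the magnitude threshold
(inclusive), preserving signs. The $O(n^3)$ trio loop is compiled (Rcpp);
an independently coded naive R loop serves as the test oracle.

Topology uses unweighted shortest paths: degree, closeness within each
connected component, harmonic closeness (defined across components), and
normalized betweenness — igraph provides all four. The best TF trio is
found by exhaustive enumeration of all TF triples, scoring the union of
direct neighborhoods minus the trio itself; ties prefer the larger summed
absolute incident edge weight, then lexicographic ids. Direct (path-length
1) coverage matches the "potentially regulated" reading of TF-target
relations; greedy selection is provably suboptimal on bundled fixtures.
Targets are classified repressed or induced by the sign of the TF-target
edge; zero-weight edges are excluded with a warning.

## The synthetic cohort

The generator emulates the study design the analysis assumes: by default
1,011 cows in 85 herd-date groups with parity and DIM classes, 37,568
biallelic SNPs on 29 autosomes, 15 traits in three residual-correlation
clusters with $h^2$ spanning 0.1–0.8, and optional major QTL specified as
fractions of a trait's additive variance (a casein-cluster-like locus at
up to ~70% is one configuration; the demo uses 50%).

Choices a user should know about:

* **Relatedness.** Cows are drawn from `n_sires = 40` paternal half-sib
  families (recombined sire gamete plus a population dam haplotype).
  This mirrors an artificial-insemination dairy cohort and is what makes
  GRM-based variance components estimable: with fully unrelated
  individuals the sampling SD of $\hat h^2$ at $n = 500$ / 2,000 SNPs is
  ~0.17, versus ~0.08–0.11 with families. Per-site Hardy–Weinberg
  proportions are preserved.
* **Scale.** Per-trait variance (fixed effects aside) is normalised to 1,
  $\sigma_g^2 = h^2$, $\sigma_e^2 = 1 - h^2$. Fixed-effect class SDs
  default to 0.5 (herd) and 0.3 (parity, DIM) — the design specifies the
  classes, not their magnitudes, so these are package choices.
* **Trait correlations.** Within-cluster residual correlation defaults to
  0.6; the emulated study reports three correlation clusters but not
  their magnitudes, so the value is a free parameter of the config.
* **LD.** Haplotypes follow a first-order Markov copy process
  (`ld_decay`), giving block-like LD without coalescent realism. QTL
  effects are assigned to a tagged chip marker, so there is no
  tag-vs-causal attenuation.
* **Polygenic values** are drawn from $N(0, K\sigma_g^2)$ with the same
  (normalised) GRM estimator the analysis uses — simulation and inference
  share one genetic model by design, which is exactly what parameter
  recovery should assume and test.

What passing tests on this cohort do **not** show: robustness to
coalescent LD, ascertainment bias of real chips, non-normal residuals,
selection, or causal variants absent from the panel. The generator is a
correctness instrument, not a population-genetic forecast.

## Problem sizes and numerical conventions

The test and acceptance workloads use: GRM moments at $n = 200$ / 5,000
SNPs; REML recovery at $n = 500$ / 2,000 SNPs, $h^2 \in \{0.2, 0.5,
0.8\}$, 20 replicates (recovery is judged by the mean estimate across
replicates — per-replicate error has an irreducible sampling SD of
roughly 0.1 under this design); null calibration at $n = 500$ / 10,000
SNPs; power and conditional behaviour at $n = 1{,}000$ / 2,000 SNPs with
a 50%-variance QTL; permutation calibration at $n = 120$ with $R = 200$
over 50 repeats; and the end-to-end demo at 300 cows / 3,000 SNPs / 6
traits with $R = 500$. These sizes keep a full run to a few minutes on
one CPU while leaving every statistical property measurable.

Determinism: every stochastic step is governed by one seed; writers emit
fixed-format text (C-locale numerics, LF line endings), and the pipeline
manifest records MD5 checksums so a re-run can be verified byte for byte.

## Known limitations

Single-GRM models only (no repeated measures, dominance, or X-dosage);
PLINK bed/bim/fam and TSV dialects only (no VCF); no gene-length-aware
enrichment; the TF trio considers direct neighbours rather than longer
range spanning; PCIT is first-order only. The conditional scan treats
lead SNPs as fixed, so its variance decomposition is descriptive rather
than causal.
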