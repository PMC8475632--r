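---
title: "Methods: haplotype-block mapping and the population-structure association test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-block mapping and the population-structure association test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psassoc)
```

## Scope and assumptions

`psassoc` analyzes panels of fully inbred (homozygous) strains. This single
assumption shapes the whole data model: each strain carries one allele per
site, so genotypes are coded per strain per site as 0 (reference), 1
(alternate) or missing, and "haplotypes" are directly observable allele
strings rather than phased estimates. Heterozygous or ambiguous diploid
calls carry no usable information for an inbred strain and are masked to
missing on import rather than rejected, mirroring the tolerance implied by
the per-site unambiguous-call filter described below.

The package's object of study is the interplay of two analyses on the same
panel:

1. a **trait association** scan over haplotype blocks (the mapping stage),
   and
2. a **population-structure (PS) association test** applied to each
   candidate block, with PS as the *response*.

The second is the core statistic. The conventional treatment of PS in GWAS
puts structure covariates on the right-hand side of the trait model. For
small homozygous panels that correction can silently discard true causative
loci whose alleles are co-inherited with sub-population membership, so here
the question is inverted and made explicit: *does this block's strain
partition look like the panel's genome-wide structure?* The answer (PS⁺ or
PS⁻) annotates, rather than filters, the mapping output.

## Haplotype block construction

Sites entering block construction must be polymorphic among the strains
with trait data and have at least `min_called = 8` unambiguous calls; both
filters operate after restriction to the phenotyped strains, so a site that
is polymorphic panel-wide but constant within the analyzed subset is
dropped.

A block is an interval of at least 4 consecutive SNPs over which the
strains with complete calls fall into *d* ∈ [2, 5] distinct allele
strings. The construction is *maximal*: an interval is emitted only if
extending it by one SNP on either side (within its chromosome) would push
the distinct-string count above the block's haplotype budget
`max(2, d)`. This realization has the properties the method requires —
blocks of different haplotype counts may overlap, and a SNP joins a block
only when it adds a haplotype — without imposing any upper bound on block
length, since none is part of the definition. Blocks with 2–5 haplotypes
are pooled in one output list. After emission, a block nested inside a
strictly larger block carrying the *identical* strain partition is removed;
with complete calls such nesting cannot actually arise under the
maximality rule (any one-column extension with an unchanged partition would
contradict maximality), so the removal pass matters only under missingness
and as a duplicate guard.

Numerical/degenerate choices:

* The rightward scan for each start column stops at the first column whose
  inclusion exceeds 5 distinct strings. With complete calls the
  distinct-string count is nondecreasing under extension, so this is exact
  (and the test suite verifies equality with exhaustive enumeration on
  random panels). With missing calls the count need not be monotone —
  a strain dropping out can merge strings — and the first-exceedance stop is
  the documented deterministic behaviour.
* Strains with any missing call inside a block are *unassigned* (label
  `NA`) rather than imputed, and unassigned strains are ignored when
  counting distinct strings; imputation would manufacture haplotypes, and
  counting incomplete strings would inflate the haplotype count.
* Blocks are ordered by (chromosome, start, haplotype count), making the
  output order reproducible.

## Trait association, effect size and power

The association statistic is a one-way ANOVA of per-strain *mean* values
across the block's haplotype groups (groups without an assigned,
phenotyped strain are dropped). Replicate-level values are deliberately not
used at this stage — they inform only dataset QC — because the mapping unit
is the strain, and strain means are what survey databases report.
Categorical phenotypes are integer-coded and run through the same F
machinery.

The sums of squares are computed explicitly (rather than through a linear
model fit) because two quantities besides the p-value are needed: the
effect size η² = SSB/SST, and an exact account of **perfect separation**.
When the within-group variance is exactly zero with unequal group means —
e.g. a binary phenotype whose affected strains coincide exactly with one
haplotype — the F statistic is unbounded and the p-value is *exactly 0*,
reported with an explicit `F_unbounded` flag instead of a numeric
underflow. This keeps downstream sorting well-defined and matches how such
complete correlations are conventionally reported. The constant-phenotype
limit (SST = 0) returns F = 0, p = 1, and η² is undefined (an error) only
when explicitly requested from a degenerate fit.

Power uses the noncentral-F formulation: with k groups, n strains and
effect size η², the noncentrality is λ = nη²/(1−η²) and

> power(α, η², n, k) = P( F(k−1, n−k, λ) > F_crit ),  F_crit = q_F(1−α; k−1, n−k).

The inequality is the *upper* tail by construction: only the upper tail
satisfies power = α at λ = 0 and grows with λ. (Written with the opposite
inequality the same expression is the type-II error; the package documents
and implements the power direction.) The λ formula is derived under equal
group sizes and is applied as stated for unbalanced groups too; at the
panel sizes involved the approximation error is far below the Monte-Carlo
tolerance the tests enforce (±0.01 at 10⁵ replicates).

Dataset QC follows the screening rules used for strain survey data: every
strain's summary must come from **more than 5** animals (a strain with
exactly 5 fails), and the inter- versus intra-strain one-way ANOVA —
reconstructed exactly from the per-strain (mean, SD, n) summaries — must
give p < 10⁻¹⁰. Categorical datasets are excluded from bulk runs but can be
analyzed individually. Correlated blocks are selected at *strictly*
p < 0.01, and when blocks are labeled with genes only the smallest-p block
per gene is kept.

## Population structure: matrices, PCs, and detection

The **GRM** standardizes each site's calls by its panel allele frequency,
z = (x − p̄)/√(p̄(1−p̄)), and averages z·z′ over sites; missing calls
contribute zero with per-pair denominators equal to the number of
co-observed sites, which keeps the matrix well-defined under missingness
without imputation. Monomorphic sites are skipped; there is deliberately
*no* minor-allele-frequency filter beyond that, because rare alleles in a
homozygous panel are real strain-defining variation. The **IBS** matrix is
the pairwise fraction of co-observed sites with identical alleles.

PC coordinates are the leading eigenvectors of either matrix. Two knobs
deserve explanation:

* **√-eigenvalue scaling (default).** Scores are eigenvectors scaled by the
  square root of their eigenvalues, so that the score geometry reproduces
  the matrix (at p = n, scores·scoresᵀ equals it) and multivariate tests on
  the scores weight components by the variance they explain, exactly as a
  PCA scatter plot does. Raw eigenvectors are available (`scale = "raw"`),
  and the test suite checks that GRM- and IBS-derived scores give nearly
  identical PS p-values (Spearman ρ > 0.95), so the choice is not critical.
* **Double-centering (default).** Before eigendecomposition the matrix is
  double-centered, as in principal-coordinate analysis. For the GRM this is
  a numerical no-op (its standardized site scores already sum to zero
  across strains); for the IBS matrix it removes the dominant constant
  component — the overall similarity level of the panel — which otherwise
  occupies the first eigenvector while carrying no information about
  *relative* structure. Without centering, IBS-derived PCs waste one of the
  p = 4 response dimensions on a near-constant column, and the GRM/IBS
  concordance degrades. `center = FALSE` gives the plain eigendecomposition
  (used, e.g., to verify the spectral reconstruction identity).

The default p = 4 retained PCs reflects where scree elbows fall for panels
of a few dozen strains; p is a visible parameter everywhere.

**Tracy–Widom assessment.** To ask whether a leading eigenvalue exceeds its
no-structure expectation, the eigenvalue list is normalized by
moment-matching: the effective marker count is estimated from the
Marchenko–Pastur dispersion identity, n′ = mS₁²/(mS₂ − S₁²) (S₁, S₂ the
sum and sum of squares of the m eigenvalues under consideration) — this
recovers the true marker count on simulated unstructured panels — and the
top eigenvalue is centred and scaled with the standard Tracy–Widom coupling
constants. When the observed dispersion is at or below the
Marchenko–Pastur floor (e.g. all eigenvalues equal), n′ is effectively
unbounded and the statistic is driven far negative: no excess, p ≈ 1. The
TW (β = 1) distribution function itself is evaluated through the
shifted-gamma approximation of Chiani (2014) (TW₁ ≈ Γ(k = 46.446,
θ = 0.18605) − 9.848), whose absolute CDF error (~10⁻⁴) is negligible
against the 0.05 decision threshold and which is smooth everywhere, unlike
table interpolation. Successive eigenvalues are tested by removing the top
one and repeating on the reduced set.

**Sub-populations.** Pre-determined group labels come from agglomerative
clustering of 1 − IBS cut at k clusters. Average linkage is the default —
the least shape-sensitive standard choice when the true cluster geometry is
unknown — and is exposed as a parameter rather than hard-wired. A
supervised per-PC ANOVA (`anova_on_pcs()`) quantifies which components
separate the labeled groups.

**LD pruning.** Sliding windows (half-window step) remove the
later-positioned site of any within-window pair with r² at or above the
threshold. The four conventional presets (10/50 kb × r² 0.5/0.75) are
provided; on strongly structured simulated panels clustering on the pruned
matrix reproduces clustering on the full matrix, which the suite checks.

## The PS MANOVA test

For a candidate block, the n × p matrix **y** of PC scores is modelled as
**y** = μ + Xβ + e with X the haplotype-group indicator; unassigned strains
are dropped (and listed in the fit). The test statistic is Pillai's trace
by default — the most robust of the classical MANOVA statistics when n is
a few dozen and group sizes are unequal — with Wilks' Λ selectable; both
use their standard F approximations, verified in the tests against an
independent MANOVA implementation to 10⁻¹⁰.

With n as small as 10 strains and p = 4 response dimensions, the residual
degrees of freedom n − k can fall below p, where the F approximations are
invalid (the error SSCP is singular). The test then automatically switches
to a permutation p-value of the statistic (default 10⁴ label permutations,
add-one estimator), flags the fit `method = "permutation"`, seeds the
permutation stream deterministically from the instance, and restores the
caller's RNG state. Parametric p-values were verified against 10⁵-label
permutation p-values to within ±0.02 on 20-strain instances.

The per-variant test (`variant_ps_test()`) replaces the haplotype indicator
with a two-level allele indicator and is otherwise the identical model;
variants whose minor allele is carried by fewer than 3 strains are rejected
as unanalyzable rather than tested.

**FDR control.** Within each dataset the family of correlated blocks is
adjusted by the Benjamini–Hochberg step-up procedure (the full
cumulative-minimum form, i.e. `stats::p.adjust(method = "BH")`, not the
bare pᵢ·m/i shorthand, which is non-monotone without the step-up rule).
The family size m is the number of correlated blocks of that dataset;
applying BH across datasets instead is possible by calling `bh_adjust()`
on a pooled vector. Classification is strict: p_adj < q = 0.05 ⇒ PS⁺;
the boundary p_adj = q is PS⁻ (the null of no structure association is not
rejected at the boundary).

## The synthetic panel generator

Because real strain genome databases and phenotype surveys are far beyond
desk scale, every downstream stage is exercised on simulated panels. The
generator follows the Balding–Nichols model: per site, an ancestral
frequency p is drawn uniformly from `ancestral_maf_range` (default
0.1–0.5); each sub-population's frequency is Beta-distributed with mean p
and variance F_ST·p(1−p); each strain draws one Bernoulli allele from its
group frequency, giving complete homozygous calls by construction. The
defaults emulate the composition of the commonly sequenced laboratory
panel: four sub-populations of 7, 14, 23 and 5 strains, F_ST = 0.3 (strong,
clearly clusterable divergence), 5000 sites at 1 kb spacing on one
chromosome.

A causative block is planted by overwriting ≥ 4 consecutive sites so that a
chosen carrier set shares the alternate string and all other strains the
reference string — the observable signature of a shared causative allele.
Phenotypes are built on the strain means: carrier strains are offset by δ,
strain means get Gaussian residual spread (`strain_sd`, default 1 — the
measurement unit), and each of `replicates_per_strain` (default 8,
satisfying the >5 animals QC rule) replicate values adds Gaussian
within-strain noise (`within_strain_sd`, default 0.5). δ is calibrated from
the one-way ANOVA moment identity E[SSB]/E[SST] = η²_target using the
*effective* per-strain variance `strain_sd² + within_strain_sd²/r`, so the
reported strain means — which carry replicate-mean noise — recover the
target: over 500 draws the mean realized η̂² at target 0.6 (n = 30) is
within ±0.05, and at target 0 it sits at the null expectation
(k−1)/(n−1). The default target η² = 0.6 reflects the large effect sizes
typical of inbred-strain mapping (usually > 0.3).

What the simulation does *not* emulate: linkage-map recombination and LD
decay (sites are exchangeable within a group, so "blocks" arise only where
planted), within-group pedigree/kinship beyond exchangeability,
recombinant-inbred panel designs, genotyping error, and non-Gaussian
phenotype noise. Passing tests therefore demonstrate correctness of the
statistics under the stated model, not robustness to those real-data
features. One simulation-specific artefact deserves note: with only a few
hundred simulated sites, a planted perfect-split block contributes
noticeably to the GRM itself and can drag its own PS test toward
significance; at genome-like marker counts (thousands of sites, as in the
pipeline tests) this proximal contamination is negligible, which is why
end-to-end recovery tests simulate ≥ 2000 sites.

## Problem sizes and reproducibility

The test suite runs at deliberately desk-scale sizes chosen to keep the
whole suite under a minute while leaving each statistical check
well-powered: panels of 10–48 strains, 20–2500 sites, 50 random panels for
the block-construction oracle, 1000 simulated instances for the size
calibration of the PS test (rejection rate required inside the exact 95%
binomial band around 0.05), 10⁵ permutations/replicates for the
permutation-validity and power oracles, and 100–500 seeds for parameter
recovery. Every simulation is deterministic given its `seed`; rerunning a
pipeline with the same configuration reproduces every output file
byte-for-byte.

## Known limitations

* The maximal-block scan's first-exceedance stopping rule is exact only for
  complete calls (see above); with heavy missingness some distant
  re-qualifying intervals are not enumerated.
* The Tracy–Widom normalization is a moment-matched approximation; for
  panels of fewer than ~10 strains its p-values should be read
  qualitatively.
* The PS test inherits MANOVA's sensitivity to grossly non-ellipsoidal
  score distributions; with one strain per haplotype group (singletons) the
  permutation fallback, not the F approximation, carries the inference.
* BH adjustment treats the blocks of a dataset as the family; overlapping
  blocks are correlated tests, so the realized FDR is conservative rather
  than exact.
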