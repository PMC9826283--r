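---
title: "Partitioning phenotypic variance in ecotype contact zones: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning phenotypic variance in ecotype contact zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `invclinal`, the
assumptions it makes, the numerical choices in its solvers, what the
synthetic contact-zone generator does and does not emulate, and the known
limitations. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The scientific setting

Two locally adapted ecotypes of a low-dispersal organism meet along a
transect crossing a habitat transition (in the motivating system, Crab and
Wave ecotypes of a marine snail along a wave-exposure gradient). Snails are
sampled densely along the transect, genotyped at thousands of SNPs with a
linkage map, scored for a set of quantitative traits, and karyotyped for a
panel of polymorphic chromosomal inversions. The analytical question is a
variance decomposition: for each trait, how much of the phenotypic variance
across the transect is explained by inversion karyotypes (large-effect
loci), by polygenic variation in the collinear genome outside inversions,
by sex, and by environmental covariates (habitat, shore height, position)?

## The animal model

For one trait at one site the model is

$$ y = X\beta + u + e, \qquad u \sim N(0,\, A\,\sigma^2_A), \qquad
   e \sim N(0,\, I\,\sigma^2_e), $$

with $y$ the z-scored trait, $X$ the fixed-effect design and $A$ a genomic
relationship matrix computed from SNPs *outside* the inversion regions.
Standardizing the response means $\sigma^2_A$ is interpretable as the
narrow-sense heritability contributed by the genomic background, and fixed
effects are comparable across traits. Key modelling assumptions:

- additive genetic effects only; dominance and epistasis are absorbed into
  the residual;
- inversion effects are additive in arrangement dosage (0/1/2) and enter as
  fixed effects, so they are *excluded* from $V_A$ both by design (fixed
  terms) and by construction of the GRM (marker exclusion with a buffer);
- residuals are homoscedastic along the transect.

### Design construction

`build_design()` z-scores every covariate (sample SD, $n-1$ denominator)
and replaces missing covariate values with 0, the mean of the standardized
scale — equivalent to mean imputation that neither shifts nor inflates the
estimated effect. Sex is coded 0/1 and then z-scored like everything else.
Interaction columns are products of the *standardized* main effects and are
not re-standardized, so a coefficient on `habitat:shore` reads as the
change in the habitat slope per SD of shore height. Samples missing the
response are dropped before any standardization, and all standardization is
within one site's samples, because sites are analysed separately.

### GRM estimator

`compute_grm()` implements the Yang et al. SNP relationship estimator:
off-diagonals $\frac{1}{m}\sum_k (x_{ik}-2p_k)(x_{jk}-2p_k)/(2p_k(1-p_k))$
and the estimator's distinctive diagonal
$1 + \frac{1}{m}\sum_k (x_{ik}^2-(1+2p_k)x_{ik}+2p_k^2)/(2p_k(1-p_k))$,
which corrects the within-individual sampling term. Choices:

- allele frequencies are estimated from the analysed samples of the site —
  there is no external reference panel in this design;
- missing dosages are mean-imputed to $2p_k$ per SNP before accumulation
  (imputed entries contribute zero to off-diagonals);
- SNPs inside any inversion region, extended by a closed 5 cM buffer on
  both sides, are removed by `select_background_snps()`; the buffer guards
  against residual linkage disequilibrium with the arrangement. SNPs with
  no map position cannot be checked against the buffer and are excluded
  from GRMs when `drop_unmapped = TRUE` (they remain available for
  karyotyping);
- monomorphic SNPs are dropped with a warning rather than producing 0/0.

Because the estimator is a per-SNP average, the marker-count-weighted sum
of per-linkage-group GRMs reconstructs the all-SNP GRM exactly; the test
suite asserts this identity at 1e-10, and it is what makes the per-LG
variance decomposition internally consistent.

### REML solvers

**Single GRM (the standard fit).** With one relationship matrix the
likelihood is profiled exactly: eigendecompose $A = U D U'$, rotate $y$ and
$X$ by $U$, and for a variance ratio $\lambda = \sigma^2_A/\sigma^2_e$ the
covariance is diagonal with weights $1+\lambda d_i$. GLS estimates and the
residual variance then have closed forms, leaving a one-dimensional REML
profile maximized over $\log\lambda \in [-12, 12]$ with `optimize()`
(tolerance 1e-10), compared against the exact boundary evaluation at
$\lambda = 0$. When the boundary wins, $\sigma^2_A$ is reported at the
floor $10^{-8}\,\mathrm{Var}(y)$ with `boundary = TRUE` rather than exactly
zero, keeping downstream covariance matrices invertible. A GRM whose
eigenvalues are (near-)constant — e.g. the identity — makes
$\sigma^2_A$ and $\sigma^2_e$ unidentifiable and triggers a warning.

**Several GRMs (per-linkage-group decomposition).** Average-information
REML over $\theta = (\sigma^2_1, \ldots, \sigma^2_L, \sigma^2_e)$ with
$V = \sum_l \theta_l A_l + \theta_e I$: score and AI matrix from the
projection matrix $P$, Newton-like AI updates, and an EM update whenever
the AI step leaves the feasible region (components floored at
$10^{-8}\,\mathrm{Var}(y)$). Convergence is declared when the relative
log-likelihood change falls below 1e-8; non-convergence within 100
iterations is flagged, never silently accepted. A single-component AI fit
agrees with the eigen solver to 1e-6, which the tests assert.

The REML log-likelihood convention includes the $-\tfrac12 (n-p)\log 2\pi$
constant and omits the arbitrary $\log|X'X|$ term consistently across the
mixed and fixed-effects-only fits, so likelihood-ratio statistics between
them are valid.

### Inference

- **Conditional Wald tests** (`wald_tests()`): each term's coefficient
  block is tested given all other terms,
  $F = \hat\beta_g' C_g^{-1} \hat\beta_g / q$ with denominator degrees of
  freedom $n - \mathrm{rank}(X)$. This is a deliberate simplification of
  proprietary mixed-model denominator-df approximations; with several
  hundred samples and a handful of variance parameters the difference is
  negligible, and the simulation calibration (empirical size within
  [0.035, 0.065] at the 5% level over 1000 null replicates) is checked in
  the acceptance suite rather than assumed.
- **$V_A$ significance** (`lrt_va()`): twice the REML log-likelihood gap
  between the model with and without the genetic component, referred to
  $\chi^2_1$. Because the null value lies on the boundary of the parameter
  space, the 1-df reference is conservative (the correct reference is the
  half-half mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, available via
  `mixture = TRUE`); the default follows the conventional 1-df report.
- **Multiple traits** (`fdr_adjust()`): Benjamini–Hochberg step-up within
  each term's group of traits, delegated to `stats::p.adjust`.
- **Collinearity** (`vif()`): classical variance inflation factors from
  regressing each design column on the others. Habitat, distance and
  clinal inversions are intrinsically correlated in a contact zone; the
  VIFs quantify how much, and exact collinearity reports `Inf` rather than
  an arbitrary large number.

### Variance partitioning

`partition_variance()` computes, for each fixed-effect term group $g$, the
sample variance of its partial predictor $X_g\hat\beta_g$ across the
analysed individuals (the standard fixed-effect variance of mixed-model
variance-decomposition practice), the variance of the summed inversion
predictor (combined inversions, including their mutual covariances), $V_A$,
and the residual variance, all divided by the observed sample variance of
the analysed response. Two deliberate bookkeeping choices:

- covariances between term-group predictors are reported as one explicit
  `fixed_covariance` line (twice the summed pairwise covariances) instead
  of being attributed to terms — no attribution rule is defensible, and
  antagonistic predictors (negative covariance, e.g. shore height versus
  inversions acting in opposite directions on a shape trait) must remain
  visible with their sign;
- the gap between the observed total variance and the model-implied sum
  appears as an `unattributed` line, so the reported proportions sum to
  exactly 1 and nothing is silently rescaled.

The observed (not model-implied) total is used as the denominator because
it makes proportions comparable across traits after z-scoring; with a
standardized response it is 1 by construction.

## The environmental and spatial modules

The **habitat PC** summarizes three binary indicators (substrate
bedrock/boulder, barnacle presence, fucoid presence) as the first principal
component of the centered, unit-scaled indicator matrix — correlation-style
PCA, chosen because the indicators are on comparable binary scales; the
covariance-matrix alternative would weight indicators by their prevalence.
The sign is fixed so wave-exposed combinations score high. Samples receive
the score of the nearest survey point along the path (ties to the lower
position; out-of-range samples take the nearest endpoint with a warning).
Note the assigned score is a noisy measurement of the underlying habitat:
single survey points carry Bernoulli indicator noise, which attenuates the
estimated habitat effect relative to the generative one — a property of
the field design, not of the estimator, and visible in the simulation
recovery results.

**Ecotype contrasts** use only samples labelled Crab or Wave (transition
excluded) and report (mean Crab − mean Wave)/mean Crab with a percentile
bootstrap CI (default 10,000 iterations) resampling within ecotypes —
the simplest interval consistent with a plain bootstrap description; BCa
would require acceleration estimates that add nothing at these sample
sizes.

**Relatedness profiles** report, for each individual, the median GRM entry
to all neighbours within 1, 2, 3, 5 and 10 m along the path; medians,
not means, because a single co-located full sib would otherwise dominate.
`transition_dip()` contrasts transition-zone and flank individuals and
localizes the minimum of a running-median-smoothed profile (window 11
samples — wide enough to suppress single-individual noise, narrow enough
to keep a ~10 m dip visible at these sampling densities; the window used is
returned in the output).

The **hybrid index** is the mean Wave-oriented allele dosage over a
user-supplied panel of diagnostic loci divided by 2 — a deliberate
simplification of likelihood-based hybrid-index estimators, adequate for
colouring individuals along the transect but not for formal admixture
inference.

## Inversion karyotyping

`region_pca()` restricts the genotype matrix to SNPs inside a region
(linkage-group match, closed cM interval), mean-imputes missing dosages and
takes principal components of the centered (unscaled) matrix. Dosages are
left unscaled because divergent SNPs are exactly the ones that should
dominate PC1; unit-scaling would up-weight uninformative markers (the
scaled alternative was evaluated and changes little).

`call_karyotypes()` clusters PC1 into three groups with `kmeans`
(25 restarts under a fixed seed), orders clusters by centre, and by default
refines the labels with an EM fit of the two-arrangement binomial mixture:
each karyotype class $k \in \{0,1,2\}$ implies dosage
$\mathrm{Bin}(k, q_{1j}) + \mathrm{Bin}(2-k, q_{0j})$ at SNP $j$, and the
EM estimates arrangement allele frequencies $q_{0j}, q_{1j}$ and class
priors, then assigns by maximum posterior. The refinement matters only
when arrangements are weakly diverged: the 1-D PC1 projection discards
multilocus information and its misclassification rate approaches the
information-theoretic limit a full-likelihood assignment attains. At high
divergence both agree exactly. Diagnostics per region: cluster centres and
sizes, a separation score (smallest centre gap over pooled within-cluster
SD), and the heterozygosity check — under Hardy–Weinberg arrangement
proportions the middle cluster must show the highest mean observed
heterozygosity at region SNPs; violation warns but does not relabel, since
automatic relabelling could mask genuinely aberrant regions.

Orientation of the dosage (which homozygote is "2") is not identifiable
from clustering alone; a reference group (by default, samples from the
Wave habitat) fixes it so dosage counts the arrangement commoner at the
Wave end. Recoding 0↔2 flips the sign of fitted inversion effects but
leaves their test statistics unchanged, which the tests assert.

Complex regions carrying a rare third arrangement are handled by
`collapse_complex()`: the analysis uses copy number of one declared focal
arrangement, so rare-arrangement carriers contribute their focal count
only. Automatic three-arrangement discovery is out of scope.

## The synthetic contact zone

`simulate_contact_zone()` generates datasets with the statistical structure
the analysis assumes, plus ground truth, so every stage is testable without
field data.

**What it emulates.** A 1-D transect from Wave (position 0) into Crab
habitat; founders placed uniformly; generations of spatially local mating
(mates drawn with Gaussian weight in distance, offspring displaced by the
same SD — default 5 m, reflecting very limited snail dispersal);
recombination of background SNPs over a 17-linkage-group map with Poisson
crossover counts in map length and uniform crossover positions (Haldane, no
interference — the simplest standard model); logistic clines in inversion
arrangement frequency with configurable centre, width and end frequencies;
region SNPs with arrangement-specific allele frequencies differing by a
configurable divergence; binary environmental indicators as noisy step
functions of the habitat; and a trait assembled from sex, habitat
plasticity, shore height, per-inversion additive effects, a polygenic
breeding value built from the background SNPs, and Gaussian residual.
`default_paper_like_config()` mirrors the motivating three-island design:
site sizes 379/381/370, path lengths 362.47/257.00/270.17 m, 16 inversions
on a 17-LG map.

**Design shortcuts, stated plainly.**

- *Clines are imposed, not evolved.* Arrangement frequencies follow the
  configured cline at the sampled generation directly (karyotypes and
  region haplotypes are drawn conditional on local cline frequency), a
  soft-selection shortcut: the analysis needs the spatial genotype pattern,
  not the selective process that produced it. A corollary is that region
  haplotypes never recombine across arrangements, which is the defining
  property of inversion polymorphism the karyotyper relies on.
- *Components are scaled to exact shares.* Each generative component is
  rescaled so its sample variance equals its target share of a nominal unit
  total. Because clinal components (inversions, habitat) covary, the
  realized total variance exceeds 1 and realized shares differ from the
  nominal targets; `SimTruth` stores the realized shares (component
  variance over realized variance), which is what recovery is measured
  against.
- *Mating ignores sex and selection;* sexes are assigned 50:50 after the
  fact, and shore height is drawn independently of position. The putative
  sex-determining region is not modelled.
- In the *secondary-contact scenario* (used for the relatedness-dip
  analyses), final-generation individuals landing in the transition zone
  are independent crosses of one Wave-flank and one Crab-flank parent —
  migrants and first-generation hybrids rather than members of locally
  breeding families — while flank individuals breed locally. This
  reproduces the empirical signature of a transient hybrid-zone population:
  reduced median relatedness to spatial neighbours.

**What passing tests do not show about real data.** The generator draws
founder genotypes in linkage equilibrium, uses a uniform map, makes
environmental noise independent across survey points, and builds the
breeding value from the same SNPs the GRM uses — the best case for GREML.
Real capture data carry LD structure, uneven marker density, genotyping
error correlated with coverage, and causal variants imperfectly tagged by
the panel, all of which would push estimates toward attenuation in ways the
simulation does not probe. Recovery results here validate the estimation
machinery, not the field-data error budget.

## Problem sizes used in validation

The test and acceptance runs use desk-scale versions of the study design,
chosen to keep each property measurable with comfortable margins: GRM
oracle equivalence at 50 samples × 200 SNPs; REML grid-search equivalence
at n = 30; full-pipeline share recovery at n = 400 with 2000 background
SNPs over 20 replicates; karyotype accuracy at n = 300 with 100 region
SNPs; Wald calibration over 1000 null replicates at n = 200; LRT size over
200 null replicates and power over 50 replicates at n = 500; the
relatedness dip at n = 400 with 6 generations of local mating.

## Known limitations

- Single-trait models only: no genetic correlations or multi-trait REML.
- The denominator-df rule for conditional Wald tests is the simple
  $n - \mathrm{rank}(X)$; small-sample df adjustments are not implemented.
- Karyotype calling assumes two arrangements per region (plus the
  `collapse_complex()` path); at very low arrangement divergence its
  accuracy approaches the information-theoretic limit of the data, and
  regions near that limit should be inspected via the returned separation
  and heterozygosity diagnostics rather than trusted blindly.
- The habitat PC inherits the survey's indicator noise; its estimated
  effect is attenuated accordingly, and no measurement-error correction is
  attempted.
- BLUP breeding values are computed (`blup()`) but are not a headline
  output; no reliability/accuracy measures accompany them.
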