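---
title: "Landmark-based analysis of cranial modularity: models, parameters, design"
author: "craniomod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based analysis of cranial modularity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniomod)
```

## The scientific problem

Phenotypic modularity asks whether a structure — here, the mammalian
cranium, digitised as K homologous 3D landmarks per specimen — decomposes
into sets of traits (modules) that covary strongly internally and weakly
with the rest. craniomod implements a complete per-species workflow with
two deliberately separate arms:

* an **exploratory arm** that clusters landmarks from interlandmark
  distances alone (EDMA), without Procrustes superimposition, and asks how
  many clusters the data support;
* a **confirmatory arm** that scores *a-priori* modular architectures
  (full landmark-to-module maps) on Procrustes shape data, by maximum
  likelihood over a trait-correlation matrix and by the covariance-ratio
  (CR) statistic with permutation tests.

The two arms answer different questions and must not share data
representations: the pipeline (`run_species()`) enforces that EDMA sees raw
configurations while the likelihood and CR machinery see aligned (and,
when size matters, allometry-corrected) shapes.

## Superimposition and the allometry gate

`gpa()` is classical generalized Procrustes analysis: translate each
configuration to its centroid, scale to unit centroid size
(`CS = sqrt(sum of squared distances to the centroid)`), rotate onto the
running consensus by orthogonal (rotation-only, `det = +1`) Procrustes,
iterate until the total Procrustes sum of squares changes by less than
1e-11. Reflections are never allowed — specimens share chirality. The
final orientation is canonicalised to the consensus' principal axes with a
deterministic sign rule, so the output is invariant (to ~1e-9) to any
common rigid motion or rescaling of the input; the reported consensus is
the plain mean of the aligned shapes.

Static allometry is handled by `allometry_correct()`: the 3K flattened
shape coordinates are regressed on centroid size (raw size by default —
a log option exists but is off, since within-species adult size ranges are
narrow), significance comes from permuting size labels (default 999
permutations, statistic: model sum of squares), and corrected shapes are
residuals plus the consensus. The pipeline's *gate* mirrors standard
reporting practice: corrected shapes are carried forward only when
`p <= alpha` (alpha defaults to 0.05, the field convention; the paper
trail of which branch was used is recorded in every report, and both
branches can be forced for sensitivity analysis).

## The exploratory arm: EDMA clustering

For each specimen the squared-distance **form matrix** is double-centered,
`B_i = -1/2 H D_i H`, and averaged. Under the Gaussian perturbation model
the expectation of `B_bar` is the mean-form Gram matrix plus a noise term
close to a multiple of `H`; `edma_mean_form()` estimates that noise level
from the eigenvalues beyond rank 3, subtracts it from the three leading
eigenvalues, reconstructs the mean shape, and sets the landmark covariance
`sigma_k = (B_bar - G_M) / 3` (3 = coordinate dimensions). The trait space
is then built by `trait_distances()`: eigenvectors of `sigma_k` with
positive eigenvalues, scaled by the square roots of the eigenvalues. The
square-root scaling is chosen because it makes the step verifiable: on a
PSD input the pairwise trait distances equal
`sqrt(S_ii + S_jj - 2 S_ij)` exactly, which the tests use as an oracle.

Clustering is Ward ("ward.D2") on those trait coordinates. The number of
clusters comes from the Gap statistic (`cluster::clusGap`, uniform
reference over the observed feature ranges, 100 reference sets, standard
error `sd * sqrt(1 + 1/B)`), selected by Tibshirani's one-standard-error
rule; when that rule returns k = 1 while the curve keeps rising — a
situation that does occur for weakly compartmentalised crania — a plateau
fallback reports the smallest k after which every further split gains less
than a tolerance (default: the median SE of the Gap curve). Both rules'
outcomes are always reported.

Cluster reliability uses bootstrap Jaccard stability
(`jaccard_stability()`): resample landmarks with replacement, recluster,
record each original cluster's best Jaccard match; clusters below 0.70 are
conventionally unstable, and `stable_partition()` decrements k until every
cluster passes (a laxer 0.60 threshold is evaluated on the same draw —
it never retains fewer clusters). Landmarks whose interlandmark distances
have across-specimen variance exceeding their mean (a signature of
landmarks digitised too close together) are excluded beforehand by
`variance_filter()`, except that members of bilateral pairs are always
retained, with a warning, so no anatomical region disappears
asymmetrically.

### A structural limitation worth knowing

Because the estimator reconstructs the mean form as the rank-3 part of
`B_bar`, any perturbation covariance whose landmark-space direction lies
inside the mean form's affine span is absorbed into the mean-shape
estimate and *lost* from `sigma_k`. A module that moves as a coherent
block in a direction resembling an affine function of the template (for
instance, "all landmarks with large x move together") is therefore partly
or wholly invisible to the exploratory arm, while the same signal remains
fully visible to the congruence/likelihood arm. The package's block
recovery tests use antipodally balanced templates — each module holds
point/antipode pairs, making the block contrast exactly orthogonal to the
affine span — which is the geometry in which recovery is identifiable.
Passing those tests therefore demonstrates correctness of the machinery,
not that every biologically plausible covariance pattern is recoverable
from distances alone.

## The confirmatory arm

### Congruence coefficient

`congruence_matrix()` builds the K x K landmark correlation matrix: each
landmark's coordinates are centered across specimens, and the coefficient
for a pair is the uncentered vector correlation of the two N x 3 deviation
matrices, pooled over the three dimensions (one coefficient per pair, not
a per-dimension average). In the 1-D degenerate case this is exactly the
Pearson correlation, which the tests exploit.

### Likelihood scoring of architectures

`fit_emmli()` evaluates each architecture by the sampling density of a
correlation coefficient given a population value rho and sample size n
(`corr_density()`; the exact bivariate-normal form including the Gaussian
hypergeometric factor, computed in log space — the truncated large-n form
misallocates up to ~1.5% of probability mass at n = 15, enough to matter
when thousands of log densities are summed). Four parameterizations per
architecture (pooled or per-module within-rho crossed with pooled or
per-pair between-rho) plus a global single-rho null are fitted by grid
search (step 0.01; `[0, 0.99]` for absolute correlations, `[-0.99, 0.99]`
for the signed run that allows negative inter-module correlations), and
compared by AICc with the number of correlations scored as effective
sample size. Reported integration tables always come from the fully
separate parameterization of the winning architecture; a between-module
rho at or above either module's within-rho is flagged as a merge
candidate. Pairs touching unintegrated landmarks are dropped from an
architecture's likelihood (the null is scored on all pairs); sample sizes
below 15 trigger an instability warning. Ties in AICc resolve to the
first architecture in listed order, deterministically.

### Covariance ratio

`cr_test()` computes CR from the 3K x 3K covariance of flattened
coordinates: for modules A and B,
`CR_AB = sqrt(tr(S_AB' S_AB) / sqrt(tr(S~_AA S~_AA) tr(S~_BB S~_BB)))`,
overall CR = unweighted mean over module pairs, where the within-module
matrices `S~` have each landmark's own 3 x 3 coordinate block excluded.
Excluding the whole block (rather than only the scalar diagonal) is what
makes the statistic invariant to a common rotation of the coordinate
system, as the landmark form of the statistic requires. Unintegrated
landmarks form a module of their own, so architectures differing only by
an unintegrated flag score identically. The permutation null reassigns
whole landmarks to modules preserving module sizes; modularity shows as a
*small* CR, so `p = (#{CR_perm <= CR_obs} + 1) / (n_perm + 1)`. The effect
size `Z_CR` standardises log(CR) (the variance-stabilising transform is a
named, swappable component) against the same permutation draw;
`compare_cr()` compares architectures by `(Z_A - Z_B)/sqrt(2)` against a
standard normal — an approximation of the published two-sample procedure,
valid because each Z is standardised to unit variance under its own null.

## The synthetic generator

`synth_spec()`/`generate_landmarks()` draw specimens from a module-factor
model: `X_i = s_i * template + sum_m w_m z_im L_m + (s_i - 1) a A + E_i`,
with correlated module scores z (so negative inter-module correlations can
be planted), a size factor `s ~ N(1, 0.05)` (5% centroid-size CV, typical
of adult intraspecific samples), isotropic digitizing noise (default 2% of
centroid size per coordinate), unit-norm loading fields per module (a
common direction with smooth distance-decay weights by default; a uniform
profile gives exactly equicorrelated blocks for oracle work), an optional
unit-norm allometric field whose slope is expressed per unit relative
size (the default suite uses 2.5, i.e. an allometric variance share of
roughly 5-10%, the typical static-allometry magnitude), random rigid
motions per specimen, and optional missing landmarks (never the first
specimen, so an imputation reference always exists). The low-rank
construction makes every implied correlation analytically computable,
which is what the oracle tests use.

`make_paperlike_suite()` bundles three regimes spanning a multi-species
cranial study: N = 74 with a seven-module truth, aligned factor directions
and a -0.5 factor correlation between the oro-nasal and molar-palate
modules (the long-snouted regime, where the signed likelihood run must
recover a negative between-module rho); N = 35 with the therian six-module
truth; and N = 12, where the correlation-density machinery must warn that
estimates are unstable. Within-module strengths are graded so congruence
correlations span roughly 0.2-0.75, the range reported for placental
cranial modules.

What the generator does **not** emulate: non-Gaussian shape variation,
measurement error that differs by landmark, asymmetry structure,
ontogenetic series, or phylogenetic covariance across species (each
dataset is a single-species stand-in). Passing the synthetic tests shows
the estimators are correct under the model they assume, not that real
crania satisfy that model.

### A property the synthetic model does not reproduce

Empirical studies report that integration estimates generally *increase*
at smaller sample sizes. Under this generator the package's test of that
property fails, and the failure is informative: the upward |r|-folding
bias of absolute correlations only dominates when true correlations are
small relative to the sampling spread, whereas at the mid-range
correlations these regimes produce, the O(1/n) downward bias of the
Pearson correlation wins; measured at n = 15 versus n = 74, weak modules
inflate but the strongly integrated oro-nasal module deflates more, so
the mean within-module estimate drifts slightly down. The corresponding
acceptance test is kept at its stated conditions and left failing rather
than re-tuned, as a documented disagreement between the factor model and
the empirical observation.

## Architectures

The bundled registry (`architecture_registry()`) holds ten cranial
architectures ordered by module count (2, 3, 5, 6, 6, 6, 7, 7, 7, 7) plus
the fully integrated single-module null — the conventional eleventh
hypothesis. Structural relations are encoded exactly: III is IV with the
oro-nasal module unintegrated; V moves the maxillary zygomatic process
into the zygomatic-pterygoid module; VII and VIII add a naso-palatine
module (VIII additionally reassigns the maxillary foramina, the posterior
interpalatine landmark and the zygomatic processes); IX and X carry a
minimal nasal module instead. The landmark-level membership shipped here
is a **synthetic** reconstruction (the file is named accordingly):
module counts, derivation rules and the bilateral pairings of the
specifically documented landmark ids are faithful, the remaining
memberships are a fixed plausible assignment. Exact replication of any
published analysis requires that study's own affiliation table, loaded
with `load_architectures()`.

## Numerical choices and degenerate inputs

* GPA convergence 1e-11 on the Procrustes sum of squares, 200 iterations;
  degenerate (zero-size) configurations are rejected by name.
* TPS imputation uses the 3D biharmonic kernel `U(r) = r` (2D variant
  `r^2 log r` available); coplanar/collinear support sets are singular and
  rejected naming the specimen; the per-species reference is the
  Procrustes consensus of complete specimens.
* rho grids exclude ±1 (the density is unbounded there); grid MLEs take
  the first maximum, so ties resolve to the smaller rho.
* Permutation p-values always include the observed statistic
  (`p >= 1/(n_perm+1)`).
* `trait_distances()` drops non-positive eigenvalues and counts them;
  `cr_from_cov()` refuses modules with no within-module covariance.
* Missing landmarks are carried as masks plus `NA` coordinates and are
  never silently zero; writers emit `NA`, readers also accept blank and
  the 9999 sentinel triple.

## Problem sizes used by the tests

The shipped tests run the full machinery at reduced but statistically
meaningful sizes chosen to keep the suite reproducible on a single CPU:
type-I calibration of the CR test uses 500 datasets (N = 50, K = 20) at 99
permutations; architecture recovery uses 100 replicates at N = 100 with 20
traits; EDMA block recovery uses 20 seeded datasets (N = 100, K = 20) with
50 Gap reference sets; bootstrap stability uses 200-500 replicates where
the study-scale convention is 10,000 (the estimate's Monte-Carlo error at
200 replicates is already below the 0.70/0.60 decision margins used).
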