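# craniomod

Landmark-based analysis of cranial modularity and integration in R.

`craniomod` is for morphometricians studying whether a skull (or any
landmarked structure) is organised into modules — sets of traits that
covary strongly with each other and weakly with everything else. It takes
multi-specimen 3D landmark data (TPS / NTS / CSV), deals with missing
landmarks, and runs two complementary analyses per species:

* **Exploratory** — Euclidean Distance Matrix Analysis (EDMA): mean form
  and landmark covariance estimated purely from interlandmark distances
  (no Procrustes superimposition), eigen-scaled trait distances, Ward
  clustering, Gap-statistic selection of the number of clusters (with a
  plateau fallback), and bootstrap Jaccard cluster stability with the
  conventional 0.70 / 0.60 thresholds.
* **Confirmatory** — scoring of a-priori modular architectures
  (landmark → module maps, unintegrated landmarks allowed) on
  Procrustes-aligned and optionally allometry-corrected shapes, by
  (1) maximum likelihood over a congruence-coefficient correlation matrix
  with AICc model selection, in absolute and signed-correlation modes, and
  (2) the covariance ratio CR with landmark-permutation tests, the
  standardized effect size Z_CR, and pairwise architecture comparison.

## The statistics at the core

For landmarks a, b with across-specimen deviation matrices A, B (N×3),
the congruence coefficient is
`r_ab = Σ A·B / sqrt(Σ A² · Σ B²)` pooled over dimensions. An
architecture's likelihood sums `log f(r | ρ̂_class, N)` over landmark
pairs, where f is the sampling density of a correlation coefficient and
each class ρ̂ is a grid MLE; architectures compete by
`AICc = −2L + 2p + 2p(p+1)/(n_corr − p − 1)`.

The covariance ratio for modules A, B over the 3K×3K shape covariance S is

    CR_AB = sqrt( tr(S_AB' S_AB) / sqrt( tr(S̃_AA S̃_AA) · tr(S̃_BB S̃_BB) ) )

with per-landmark coordinate blocks excluded from the within-module terms;
CR < 1 indicates modularity, significance comes from permuting landmarks
across modules, and `Z_CR` (more negative = stronger modular signal)
standardises log CR against the permutation distribution.

A synthetic-data module generates landmark datasets with known modular
covariance, allometry, digitizing noise, rigid motions and missing
landmarks, so every stage of the pipeline is testable against ground
truth.

## Worked example

```r
library(craniomod)

suite  <- make_paperlike_suite(seed = 42)       # study-like synthetic regimes
ds     <- suite$n35_six_module$dataset          # N = 35, 54 landmarks,
                                                # six-module ground truth
report <- run_species(ds, architecture_registry(),
                      pipeline_config(seed = 42, n_perm = 499, n_boot = 500))
report
#> <species_report> synthetic (N=35, 0 imputed)
#>   allometry: r2=0.052 p=0.02 -> corrected shapes
#>   EDMA: 4 stable clusters (gap k=4)
#>   EMMLi best: IV (mean rho 0.40)
#>   strongest CR signal: IV

round(report$emmli_abs$rho_within, 2)
#>         basicranium        molar-palate               orbit           oro-nasal
#>                0.40                0.34                0.34                0.66
#>               vault zygomatic-pterygoid
#>                0.27                0.41
```

Reading the output: static allometry explains ~5% of shape variance and is
significant (p = 0.02), so downstream statistics use allometry-corrected
shapes. The exploratory arm finds four stable landmark clusters. The
likelihood comparison across the bundled architecture registry (ten
cranial hypotheses plus the fully integrated null) selects the therian
six-module architecture **IV** — the regime's actual ground truth — with
within-module integration strongest in the oro-nasal module (ρ = 0.66),
and the CR effect sizes agree: architecture IV carries the most negative
Z_CR.

The bundled registry (`inst/extdata/architectures_synthetic.csv`) is a
synthetic structural reconstruction of ten classical cranial architectures
(2–7 modules); to replicate a specific published study, load that study's
own landmark-affiliation table with `load_architectures()`.

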