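# moesubtype

Alzheimer's disease is heterogeneous: patients with the same clinical
diagnosis differ in where their cortex thins, how fast they decline and
which biomarkers go abnormal. `moesubtype` discovers such atrophy-based
subtypes from regional cortical-thickness tables (68 Desikan–Killiany
ROIs) using a semi-supervised **mixture of experts (MOE)**: fuzzy
clustering of patients coupled with one max-margin linear
patient-versus-control classifier ("expert") per cluster, optimized
alternately. It is aimed at neuroimaging and biostatistics researchers
who have subject-by-ROI morphometry tables with a cognitively normal
(CN) reference group and want interpretable subtype models rather than
a black-box clustering.

## The model

Each ROI thickness is first residualized against a CN-only normative
regression (per ROI *j*):

```
thickness_j = β0_j + β1_j·age + β2_j·sex + β3_j·education + β4_j·ICV + ε_j
```

fitted on CN baseline scans only, then subtracted from **all** subjects
using their own covariates, so patients never influence the norm.
Residuals are standardized by the CN residual SD per ROI.

The MOE then couples, for `K` experts:

* **Experts** — instance-weighted soft-margin linear SVMs
  `min ½‖w_k‖² + C Σ_i u_ik·hinge(y_i, w_k·x_i + b_k)` with CN subjects
  (y = −1) always at weight 1 and AD subjects (y = +1) weighted by their
  fuzzy membership `m_ik` in cluster *k*. Solved exactly in the dual by
  SMO with per-sample box constraints (compiled code).
* **Mixture** — fuzzy memberships updated at sharpness `t`; by default a
  softmax over distances to *shrunken* cluster centroids (centroids
  soft-thresholded toward the CN origin, encoding that atrophy patterns
  are sparse deviations from normal), with the classic softmax over
  hyperplane signed distances available as an alternative gating.

The number of experts and the `(C, t)` grid (2⁻³ … 2¹⁰) are selected by
10-fold cross-validated accuracy of the whole model (max-expert rule),
tie-broken by the maximum pairwise inner product of expert normals
(redundancy) and the fuzzy partition coefficient (BPC). Fitted
hyperplanes then support per-subtype classifier evaluation,
cross-sectional profiling (ANOVA, Dunnett/Tukey, chi-square, CSF
abnormality proportions, per-ROI FDR effect-size maps) and longitudinal
subtype attribution with transition tables.

A synthetic-cohort generator plants four ADNI-like atrophy patterns
(occipital-sparing, left-temporal, minimal, diffuse) at the study's
published proportions so the entire pipeline is testable end to end
without access-controlled data.

## Worked example

```r
library(moesubtype)

spec   <- default_spec()                      # 228 CN + 192 AD, 4 patterns
gen    <- generate_cohort(spec, seed = 1)
ref    <- fit_reference_glm(gen$cohort)       # CN-only normative model
res    <- residualize(ref, gen$cohort)        # standardized residuals
fit    <- fit_moe(res, K = 4, C = 1, t = 2, seed = 11)

print(fit)
#> <moe_model> K = 4  C = 1  t = 2
#>   AD subjects: 192  iterations: 24  converged: TRUE
#>   subtype sizes: 26/45/58/63

glance(fit)
#> # A tibble: 1 × 9
#>       K     C     t  n_ad n_iter converged objective   bpc max_inner_product
#>   <dbl> <dbl> <dbl> <int>  <int> <lgl>         <dbl> <dbl>             <dbl>
#> 1     4     1     2   192     24 TRUE           56.0 0.966             0.454

mclust::adjustedRandIndex(fit$subtype, gen$truth$subtype_index)
#> [1] 0.8381881
```

The four recovered groups track the planted patterns closely (adjusted
Rand index 0.84 at the default 1.0-SD effect sizes; the minimal-atrophy
group, planted at 0.3 SD, accounts for most residual confusion).
Per-subtype classifiers, profiling tables and longitudinal transitions
follow with `evaluate_final_classifiers()`, `effect_size_map()`,
`attribute_followup()` and `transition_table()`; `run_pipeline()`
orchestrates all stages from one seeded configuration and writes CSV
artifacts plus a manifest. A thin command-line wrapper lives at
`inst/cli/moesubtype`.

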