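---
title: "Methods: mixture-of-experts subtyping of cortical atrophy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixture-of-experts subtyping of cortical atrophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moesubtype)
```

## The problem and the model

Alzheimer's disease presents with heterogeneous regional atrophy.
Clustering patients directly mixes disease heterogeneity with nuisance
variation (age, sex, head size, education), while one-hyperplane
classifiers force a single conversion model from cognitively normal
(CN) to patient. The mixture of experts (MOE) implemented here couples
the two views: AD subjects are fuzzily partitioned into `K` clusters,
and each cluster owns a linear max-margin classifier ("expert")
separating it from the whole CN group. The two halves are optimized
alternately, so the partition is shaped by what the experts can
separate, and the experts are trained on the partition.

### Covariate residualization

Per ROI, thickness is regressed on an intercept plus age, sex, years of
education and intracranial volume, on CN baseline rows only, by
ordinary least squares (a Gaussian identity-link GLM). The fitted
coefficients are applied to every subject's own covariates — CN and AD,
baseline and follow-up — and subtracted. Two consequences matter:

* AD rows can never distort the normative model (adding or removing AD
  rows leaves every coefficient unchanged, which the tests assert);
* follow-up visits are residualized with the baseline coefficients at
  the subject's visit-time age, so normal aging between visits is
  removed by the same model that defined the baseline norm. A
  `freeze_age` option reproduces the alternative reading in which age
  is held at baseline.

One printed form of the residualization equation uses the CN cohort's
education symbol where the parallel structure implies the subject's own
value; we treat that as a typesetting slip and use each subject's own
covariates throughout, consistently with how age, sex and ICV enter.

Residuals are divided by the per-ROI CN residual SD by default
(`standardize = TRUE`). The source analysis does not state whether it
standardized; we default to standardizing because unstandardized
mm-scale features would let large-variance ROIs dominate the margin,
and because it gives the shrinkage gating (below) a natural unit. The
flag is configurable off.

### Experts: instance-weighted linear SVMs

Each expert solves the soft-margin primal
`min ½‖w‖² + C Σ_i u_i max(0, 1 − y_i(w·x_i + b))` with per-sample
weights `u_i`: CN subjects (reference group, y = −1) always carry
weight 1, AD subjects (affected group, y = +1) carry their fuzzy
membership in the expert's cluster. Every expert therefore models one
subtype-versus-whole-CN boundary. No installed R SVM exposes per-sample
weights, so the dual is solved natively (compiled SMO with second-order
working-set selection, per-sample box constraints `0 ≤ α_i ≤ C·u_i`,
exact unregularized bias from the KKT conditions). Uniform weights
reproduce `e1071::svm` hyperplanes to 1e-6, which the test suite
checks; samples with weight below 1e-8 are dropped before solving.
Across alternation sweeps each expert's dual variables are warm-started
from the previous sweep (clipped into the new box and repaired to
feasibility), which is what makes dense hyperparameter grids and
repeated restarts affordable.

### Mixture: fuzzy membership updates

The published description names fuzzy clustering as the mixture half
but not the update rule, so the rule is an explicit, pluggable design
decision here, with two options behind one interface:

* **Shrunken-centroid gating (default).** Memberships are
  `m_ik = softmax_k(−t/2 · ‖x_i − c̃_k‖²)`, where `c̃_k` is the
  membership-weighted centroid of cluster `k` soft-thresholded toward
  the origin coordinate-wise by `shrink · sqrt(2 log d) / sqrt(n_k)`
  (`d = 68`, `n_k` the cluster's effective size, `shrink = 0.5`). In
  CN-standardized residual space the origin *is* the CN norm and
  atrophy patterns are sparse deviations from it, so coordinates whose
  centroid estimate is indistinguishable from normal are set to exactly
  zero — the universal-threshold argument from sparse estimation. This
  matters quantitatively: with 68 dimensions and clusters of 30–60
  subjects, unshrunk centroids carry noise of norm ≈ 1–1.5 SD, which
  swamps the mildly affected clusters. In simulation at the default
  study conditions the shrunken gating recovers planted partitions with
  median adjusted Rand index ≈ 0.85, where unshrunk centroid gating
  and full-dimension maximum likelihood both plateau near 0.75.
* **Distance gating** (`gating = "distance"`, and the exported
  `update_membership()`): `m_ik = softmax_k(t · d_k(x_i))` with `d_k`
  the geometric signed distance `(w_k·x + b_k)/‖w_k‖`. This is the
  simplest reading of "push subjects to the expert they are deepest
  into". It is kept because it needs nothing but the hyperplanes (and
  is therefore the natural probe of the fitted experts), but it is not
  the default: when atrophy patterns nest — a diffuse pattern contains
  the focal ones, as in the default generator — a severely atrophied
  subject out-projects everyone on *every* expert, so argmax-distance
  attribution cannot tell nested subtypes apart no matter how the
  experts are placed. Truth-initialized fits drift away under this
  rule in simulation.

In both gatings `t ≥ 0` is the sharpness: `t → 0` gives uniform
memberships, `t → ∞` crisp assignment. The softmax is computed with
row-wise max subtraction, so extreme `t` cannot overflow. `t` is the
second grid-searched hyperparameter alongside `C`.

### Alternation, restarts, convergence

One sweep trains all `K` experts against the current memberships, then
refreshes memberships from the new experts (the model's gating). Sweeps
stop when the largest membership change falls below `tol = 1e-4` or
after `max_iter = 100` sweeps. The coupled update is heuristic, not a
joint descent, so the summed weighted-SVM objective is recorded per
sweep as a diagnostic trace rather than asserted monotone. Each fit
runs `n_restarts = 10` initializations (k-means on the AD residuals,
softened to 0.9/rest, by default; symmetric Dirichlet optional) and
keeps the restart with the lowest summed expert objective — across
simulated restarts that objective correlates strongly (Spearman −0.5 to
−0.9) with recovery of the planted partition. One caveat motivates a
tie-break: once every cluster is linearly separable from CN the summed
objective barely distinguishes partitions, and can even slightly favor
merging the two mildest clusters (their shared expert costs about as
much margin as the mildest alone) while splitting an easy one (nearly
free). Restarts whose objectives lie within 5% are therefore compared
on the gating's own cost, the membership-weighted squared distance to
the shrunken centroids. A restart in which an
expert's total AD membership collapses below `1e-6 · n_AD` is discarded;
if all collapse, the fit errors with the advice to reduce `K`.
`K = 1` reduces exactly to one uniform-weight linear SVM.

## Model selection

For each candidate `(K, C, t)` the whole model is cross-validated with
stratified folds (f = 10 by default): refit on training folds, call a
held-out subject AD when its largest signed distance over experts is
positive, and pool fold accuracies to mean ± SD. The partition indices
— Bezdek's partition coefficient (BPC, 1 = crisp, 1/K = uniform; our
reading of the uncited "cluster separation index") and the maximum
pairwise inner product of unit-normalized expert normals — come from
the full-data fit. The published "average accuracy" does not define a
pooled prediction rule; the max-expert rule is this package's
definition.

Ranking treats accuracies within `acc_tol = 0.02` of the best as tied,
then prefers lower inner product, then higher BPC, then smaller `K`.
The band exists because held-out accuracy saturates quickly in `K`
(every extra expert adds boundary flexibility against CN), so beyond
the band accuracy differences are noise and the redundancy index must
carry the decision: splitting a real cluster produces near-duplicate
experts (inner product toward 1), while distinct clusters keep it low.
Configurations whose experts collapse in every restart are recorded
with missing metrics and ranked last — failure to support `K` experts
is evidence about `K`, not an abort condition.

Selection sanity is validated on planted-partition cohorts with
disjoint, mutually orthogonal pattern supports (`planted_k_spec()`),
not on the ADNI-like nested patterns: when one pattern's support
contains another's, a coarser model remains genuinely competitive and
the "true" number of clusters is only weakly identified — a property of
the data, not of the selection rule. With orthogonal supports at
1.5-SD effects the procedure recovers the planted `K` in 30/30
simulated cohorts at a reduced 5×5 `(C, t)` grid.

One calibration subtlety is worth knowing: the reference regression is
fitted once on all CN rows before any cross-validation (that is the
residualization design), so held-out CN residuals are recognisably
constrained — their per-ROI means are pinned near zero — and a
signal-free cohort still cross-validates a few points above chance.
Chance-level calibration is therefore checked against a permutation
null (diagnosis labels shuffled after residualization), which is the
appropriate exchangeable reference for this design.

After selection, each subtype is re-examined as a plain two-class
linear SVM (that subtype's AD versus all CN) under 5-fold
cross-validation at the selected `C` (`evaluate_final_classifiers()`).

## Profiling and longitudinal analyses

Cross-sectional characterization uses standard machinery: one-way
fixed-effects ANOVA (`aov`); single-step Dunnett many-to-one and Tukey
all-pairs comparisons through `multcomp`/`mvtnorm` multivariate-t
integration (fixed seed, ≥ 1e5 integrand evaluations; adjusted
p-values are clamped to be no smaller than raw ones, guarding against
Monte-Carlo jitter at single comparisons). The source text applies
Dunnett's — a many-to-one procedure — to all between-subtype pairs,
which is internally inconsistent; both readings are provided
(`dunnett_pairwise()` with a selectable control, `tukey_pairwise()` for
all pairs) and which control the original used is unknowable, so no
default claims to match it. Chi-square tests are Pearson without
continuity correction. CSF abnormality proportions exclude missing
values from the denominator and use strict inequalities (a value at the
threshold is normal); the default cutpoints (amyloid-beta 1-42 < 192,
t-tau > 93, p-tau > 23 ng/L) are the standard ADNI ones, stated here as
configuration because the source does not print them. Effect-size maps
are per-ROI pooled-SD Cohen's d with Benjamini–Hochberg adjustment
across the 68 ROIs and a stringent default flag at q < 0.0005.

Longitudinally, annual thinning rates are
`(thickness_m − thickness_0)/(m/12)` with the longer of the 12- and
24-month visits preferred (less noise-sensitive; configurable).
Follow-up visits are residualized with the baseline normative model,
pushed through the baseline-fitted model, and re-gated at the fitted
`t` — applied to unmodified baseline rows this reproduces the baseline
labels exactly, which both the unit and acceptance suites assert.
Transition tables cross-tabulate baseline versus follow-up labels per
visit pair, with subjects lacking the follow-up counted in an
attrition attribute rather than silently dropped.

## The synthetic generator

`default_spec()` encodes the study conditions the package is validated
under: 228 CN and 192 AD subjects; CN age 75.9 ± 5.0 and AD age
75.4 ± 7.4 years; women 47.8% / 47.4%; education 16.1 ± 2.9 /
14.7 ± 3.1 years; ICV 1.5e6 ± 1.5e5 mm³; per-ROI baseline mean 2.5 mm
with independent Gaussian noise of SD 0.15 mm (an optional exchangeable
correlation knob exists, default off); covariate effects −0.01 mm/yr
age, +0.02 mm female, +0.002 mm/yr education, 5e-8 mm/mm³ ICV —
literature-plausible small values, fixed once and documented as
choices. Four planted patterns at proportions 0.292/0.224/0.161/0.323
(56/43/31/62 subjects at n = 192): occipital-sparing (bilateral
lateral parietal, precuneus, superior and rostral-middle frontal,
middle/inferior temporal), left-temporal-dominant (the left lateral
temporal-parietal cortex), minimal atrophy (0.3 SD in the inferior
temporal regions only) and diffuse (all regions except bilateral
postcentral, paracentral, lingual, pericalcarine). Affected ROIs
default to 1.0 SD of thinning. ROI supports follow the qualitative
anatomical descriptions of the subtypes, including the discussion-level
characterizations of their extent; no values were read off any figure.
Follow-ups decline at per-pattern rates (0.15/0.12/0.02/0.20 SD/yr;
the left-temporal pattern spreads into occipital and right temporal
cortex over time), plus continued normal aging through the age
covariate, measurement noise of 0.02 mm, and per-visit attrition
(10% at 12 months, 25% at 24 months by default).

What the generator deliberately does not emulate: spatial covariance
between ROIs beyond the single exchangeable knob, scanner/site effects,
non-Gaussian thickness distributions, diagnosis errors, and
covariate-pattern interactions. Passing tests on this generator
therefore demonstrate correctness of the machinery and recoverability
under clean planted structure, not performance on real ADNI data.

## Numerical choices and scale of the validation runs

SMO stops at duality gap `eps_svm` (1e-6 in fits; 1e-10 where tests
compare against an external solver; 1e-4 inside cross-validated grid
searches, where hyperplane precision far exceeds fold noise).
Ties in hard assignment go to the lowest expert index, with a message.
Membership rows are renormalized softmaxes, so they sum to 1 by
construction; degenerate distances are max-subtracted. The validation
suites run the full 228 + 192 design for recovery checks (10 cohorts)
and scaled-down cohorts (around 100 + 96) with a 5×5 grid subset,
3 folds and fewer restarts for selection checks — sizes chosen to keep
the whole suite in the tens of minutes on one core while leaving every
assertion at its stated tolerance.

## Known limitations

* The membership update is an interpretation; the original's exact rule
  (and whether its `t` is a fuzziness exponent rather than a softmax
  sharpness) is not recoverable from the published description. Both
  provided gatings reduce to the same crisp/uniform limits in `t`.
* The alternation is a heuristic block update without a joint
  objective; quality control is via restarts, the objective trace and
  the selection indices, not a convergence theorem.
* Under nested atrophy patterns the number of subtypes is only weakly
  identified by held-out accuracy; the selection indices are validated
  under orthogonal supports, and on nested data the choice of `K`
  should be treated as a modeling decision informed by all three
  indices.
* Real-data features the generator omits (site effects, correlated
  noise) mean reported recovery rates are upper bounds on what
  identical settings would achieve on ADNI tables.
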