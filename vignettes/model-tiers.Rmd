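---
title: "Comparing clinical, lesion and connectome models of post-stroke depression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing clinical, lesion and connectome models of post-stroke depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Roughly a quarter of stroke survivors develop clinically relevant depressive
symptoms within months of the event. Whether the *location* of the infarct
carries predictive information beyond well-established medico-psycho-social
risk factors (sex, cognition, socio-economic deprivation, baseline mood) is
a long-standing question, complicated by the fact that a focal lesion can
disrupt distributed brain networks far beyond its borders. `psdstack`
implements a tiered comparison of predictive models of 3-month depressive
symptoms (CES-D total score, 0–60) that operationalises this question:

1. **clinical** — ten covariates (sex, age, living alone, education, NIHSS,
   mRS, MOCA, depression and anxiety self-evaluation, EPICES), ordinary
   least squares;
2. **radiological** — eight binary macroscopic location flags (frontal,
   parietal, insular, temporal, occipital, basal ganglia, cerebellum,
   brainstem; left/right merged), ordinary least squares;
3. **gray-matter**, **white-matter**, **functional-network**,
   **functional-disconnection** — per-ROI lesion loads against probabilistic
   atlases (the load is the maximal ROI probability over lesioned voxels),
   non-negative LASSO;
4. **dense-edge** and **module-wise** — the parcel-wise structural
   disconnectome, either every edge or within/between-module means,
   non-negative LASSO;
5. **topology** — fifteen graph metrics of the spared weighted network,
   sign-unconstrained LASSO.

Tiers are compared by AIC with relative probabilities
`exp((AIC_ref − AIC_i)/2)`, and finally combined into a hierarchical
meta-model by forward deviance-criterion stacking of their cross-validated
predictions.

Because the cohort that motivates this package is not publicly deposited,
the package ships a first-class synthetic-data module that generates a
statistically faithful stand-in study with planted, recoverable effects;
every quantitative claim the test suite and the acceptance script make is
computed on that synthetic study.

## The synthetic study

`synth_config()` fixes the study conditions once:

* **Cohort**: n = 233 subjects. Covariates match the summaries of a
  minor-stroke population: ~30 % female, age ~58 ± 16, MOCA median 26,
  NIHSS median 1, EPICES median ~13.6 (lognormal), depression/anxiety
  visual-analogue self-evaluations on 0–10.
* **Lesions**: one per subject (a `multifocal` flag adds a second lesion
  with probability 0.25). Volumes are lognormal with meanlog `log(1.08)`
  and sdlog `(log 2.72 − log 0.56)/(2 Φ⁻¹(0.75))`, i.e. median 1.08 mL and
  interquartile range 0.56–2.72 mL. The macro-region is sampled with
  cerebellum 16.31 % and brainstem 7.73 %; the remaining six regions share
  the rest uniformly, a choice made because only those two frequencies are
  available as printed aggregates. Each lesion is a randomly anisotropic
  discrete ellipsoid of *exactly* `round(volume/0.008)` voxels centred
  inside its region box; it may straddle into a neighbouring box, as real
  strokes straddle lobes.
* **Geometry**: a 48×56×48 voxel grid at 2 mm isotropic partitioned into 8
  labelled boxes standing in for the macro-regions. The geometry is
  deliberately crude: only region membership matters downstream.
* **Connectome**: 36 parcels in 5 functional modules (visual, somato-motor,
  salience, cognitive-control, default-mode), placed at random distinct
  voxel centers and assigned round-robin. Fiber counts are Poisson with an
  exponentially distance-decaying mean (length scale 25 mm) enriched ×4
  within modules; each fiber is materialised as a jittered 5-point
  polyline, so the fiber-count matrix equals the streamline count by
  construction, and disconnected components are bridged through their
  nearest centroids. This is roughly a third of the parcel count a real
  normative connectome would use — chosen so the whole pipeline, including
  repeated nested cross-validation, runs in minutes on one CPU; nothing in
  the code depends on this scale.
* **Outcome**: CES-D = 14.5 + Σ effect·predictor + N(0, 6), clipped to
  [0, 60] and rounded. Planted defaults: sex +1.38, EPICES +0.05/unit,
  MOCA −0.20/unit, depression self-evaluation +2.00/unit, frontal +2.84,
  cerebellar +2.18 — and a hub-disruption effect of +30 CES-D points per
  unit of normalised maximal betweenness-centrality drop. The intercept and
  noise were chosen once so the CES-D median lands in the target 13–20.25
  band and the clinical tier explains roughly a fifth of the variance.

Two planting choices deserve emphasis. First, the location effects act on
the *realised* region flags of each mask (a straddling lesion with a
frontal component counts as frontal), which is what the radiological tier
sees, so those coefficients are exactly recoverable. Second, the topology
effect is planted *through the package's own machinery*: each subject's
lesion is converted to a disconnectome, the spared graph's maximal
betweenness centrality is compared with the normative graph's, and the drop
enters the linear predictor. This circularity is deliberate and documented:
it guarantees the topology tier's feature contains the planted signal, at
the price of saying nothing about whether real depression relates to hub
disruption. With paper-faithful 1 mL lesions only ~15–20 % of subjects show
any betweenness drop at all, so the topology tier is intentionally weak
under defaults — small strokes rarely hit network hubs.

What the generator does **not** emulate: anatomy (boxes are not lobes),
spatial autocorrelation of stroke across subjects, registration error,
multi-site effects, longitudinal change, non-Gaussian symptom noise, and
missingness. Passing tests therefore demonstrate that the *pipeline*
recovers what was planted under its own assumptions — not that those
assumptions hold in patients.

## Disconnectome geometry

The parcel-wise disconnectome is `D[i,j]` = (streamlines of edge {i,j}
passing through the lesion) / (fiber count), in [0, 1]. Streamline–lesion
intersection uses an exact Amanatides–Woo voxel traversal (compiled): every
voxel a polyline segment passes through is enumerated, so there is no
sampling step to tune and no way to skip a grazed corner. We preferred this
over fixed-step sampling because it makes oracle tests well-posed: a
brute-force segment–box intersection over every lesioned voxel must agree
*exactly*, and the test suite checks that it does. Voxelwise disconnection
maps report, per voxel, the fraction of traversing streamlines that hit the
lesion, binarised at ≥ 0.5 (inclusive). The spared graph is
`W ⊙ (1 − D)`, which keeps the fiber-count scale.

## Topology metrics

Fifteen metrics per subject on the spared weighted undirected graph: global
efficiency, characteristic path length, mean Onnela clustering, weighted
transitivity, modularity Q *evaluated at the fixed module partition* (not
re-optimised), strength assortativity, density, mean strength, maximal
betweenness centrality (normalised by `(n−1)(n−2)/2`), the maximal
betweenness drop versus the normative graph, and the local efficiency of
each of the five functional modules (global efficiency of the induced
subgraph). A config switch computes the metrics on `D` itself instead of
the spared graph, since either reading of "computed for individual
parcel-wise structural disconnectomes" is defensible; the spared graph is
the default because it retains the normative scale.

Distances are `1/(w/wmax)` (a `-log` variant is available). One numerical
subtlety: rescaling each graph by its *own* maximum would break the
invariant that lesions can only decrease efficiency — shrinking the
strongest edge inflates every other rescaled weight. `compute_topology()`
therefore normalises the spared and normative graphs by their *common*
maximum, which restores monotonicity and makes efficiencies comparable
across subjects; the standalone helpers default to the per-graph maximum.
Infinite distances (disconnected pairs) contribute zero to efficiencies and
are excluded from the characteristic path length; a fully disconnected
spared graph is an error only when it is entirely zero.

## Fitting, validation and comparison

* **Cross-validation** is repeated stratified k-fold (10 × 10 by default),
  stratified on CES-D tertiles with boundary ties to the lower bin. Folds
  are dealt per stratum round-robin over folds ordered by current load, so
  per-stratum fold counts differ by at most one and every fold's tertile
  count is within one subject of its proportional share.
* **Out-of-sample R²** refits the model inside every training fold — for
  LASSO tiers the penalty is reselected inside the training fold by an
  internal single-repetition stratified CV (5-fold by default, a
  cost/stability compromise) — pools held-out predictions per repetition,
  and averages `1 − SS_res/SS_tot` over repetitions. It may legitimately be
  negative.
* **LASSO** uses coordinate descent on a log-spaced penalty grid truncated
  at `λ_max/100` (the far tail is never selected by CV and only costs
  convergence trouble on collinear topology features), CV-min rule by
  default, 1-SE rule behind a flag. Non-negativity (lesion load can only
  add risk) holds for all atlas and disconnection tiers; the topology tier
  is unconstrained because metrics can plausibly cut both ways. The final
  coefficients are an exact refit at the chosen penalty with a 1e-12
  convergence threshold, and the test suite checks the KKT conditions at
  1e-6. An empty selection is a valid null fit predicting the outcome mean.
* **AIC** is Gaussian, `n·log(RSS/n) + 2(k+2)`, with k the number of
  predictors (GLM) or of non-zero coefficients (LASSO) — the standard LASSO
  degrees-of-freedom result. Only AIC *differences* are meaningful, and the
  comparison table reports `exp(−ΔAIC/2)` against the best and against the
  intercept-only null, with the conventional ΔAIC > 2 / > 4 support labels.
* **NBS**: per-edge univariate F statistics (zero-variance edges excluded),
  a primary threshold (default per-edge p = 0.001; configurable), connected
  components of the suprathreshold graph, and a permutation null of the
  maximal component statistic with `p = (1+count)/(1+n_perm)`. Both the
  classic *extent* (edge count) and *intensity* (sum of F − threshold)
  statistics are implemented. On small graphs extent is heavily tied —
  the max component size is a small integer — which makes its p-values
  conservative; intensity has a continuous null upper tail and is the
  better-calibrated choice there, which is how the calibration test
  exercises it.

## Hierarchical stacking

The meta-model is a forward stepwise regression whose regressors are the
subordinate models' *out-of-fold* prediction vectors (using in-sample
predictions would let an overfit subordinate dominate; a switch allows the
in-sample variant for strict emulation of the original procedure).
From the intercept-only null, each step adds the unused prediction with the
largest deviance drop iff the chi-square test on the scaled Gaussian
deviance difference `n·log(RSS_old/RSS_new)` (df = 1) is significant at
α = 0.05; ties break to the lower model index. The final model is refit by
least squares, so its in-sample R² dominates every subordinate's marginal
R² whenever at least one model is accepted. The stack's own out-of-sample
R² follows the same convention as the GLM tiers: the model (here, the
selected set of prediction vectors) is fixed and only its weights are refit
inside every training fold. A stricter evaluator that re-runs the forward
selection per fold — charging the meta-model for selection instability as
well — is available via `reselect = TRUE`; it is noticeably noisier, which
is why it is not the default.

## Problem sizes used by the tests

The unit suite exercises a 15-parcel connectome on a 24×28×24 grid; oracle
equivalence uses 20 random lesions (disconnectome) and 50 random ≤ 8-node
graphs (topology); parameter recovery runs 100 cohorts at n = 233; NBS
calibration runs 200 permuted-outcome studies at 500 permutations each; the
stacking property runs 5 full pipelines at n = 233 with 3×10 CV. These
sizes keep the whole suite within a coffee break on one CPU while leaving
every statistical check adequately powered.

## Known limitations

* The atlases are synthetic Gaussian-blob stand-ins; real probabilistic
  atlases plug in through `atlas()` / `read_atlas()` but are not shipped.
* The normative connectome is geometric, not tractographic; TRK/TCK import
  is out of scope (a plain-text streamline format is documented in the
  README).
* The voxelwise disconnection map is a reporting artifact; only the
  parcel-wise disconnectome feeds models.
* Gaussian linear models throughout; ordinal or logistic outcomes, elastic
  net, mixed models and backward/bidirectional stepwise are non-goals.
* With the default planted effects the dense-edge, module-wise and
  functional-disconnection tiers are expected to select nothing — that is
  the faithful behaviour, not a bug.
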