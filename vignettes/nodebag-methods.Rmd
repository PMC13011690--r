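---
title: "Attention-guided multiple instance learning for lymph-node metastasis prediction: methods and design notes"
author: "nodebag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nodebag methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# Overview

`nodebag` implements a CT-based prediction framework for lymph-node
metastasis (LNM) in esophageal cancer and the downstream treatment
decision it supports: whether a patient is likely to benefit from
postoperative adjuvant therapy (POAT). The scientific premise is that a
patient's nodal status is a *bag-level* property: a patient is
node-positive if **any** of their lymph nodes harbors metastasis, but
per-node ground truth is unavailable at training time — only the
patient-level label is known. This is exactly the multiple instance
learning (MIL) setting, and the package's core is a hand-written
attention-based MIL network over bags of lymph-node feature vectors.

Around that core the package provides the full study pipeline:

1. a synthetic cohort generator (patients, lymph-node bags, two feature
   views, clinical covariates, survival with a treatment effect);
2. phantom CT volumes and a compact radiomics engine (first-order,
   GLCM, GLRLM, GLSZM, GLDM, NGTDM, mesh-based shape);
3. reproducibility-and-redundancy feature selection (ICC, Spearman
   filtering, LASSO);
4. five base sub-models (two MIL, two tumor-level SVMs, one clinical
   SVM) plus a largest-node baseline;
5. decision-level stacking with out-of-fold meta-features;
6. evaluation (Mann–Whitney AUC with DeLong CIs, Youden cutoffs,
   confusion metrics, decision-curve analysis);
7. risk-stratified survival analysis localizing the POAT benefit.

Everything is exercisable offline on synthetic data; no real imaging or
patient data is required or included.

# The synthetic cohort generator

Because the package must be testable end to end, it ships a generator
whose *ground truth is known by construction*. Design decisions:

- **Bag structure.** Each patient has `1 + Poisson(7.7)` lymph nodes
  (mean ≈ 8.7). A patient is node-positive with probability 0.62
  (marginal prevalence before the clinical tilt). For positive
  patients, the number of truly metastatic ("witness") nodes is drawn
  from a zero-truncated Binomial(n, 0.3), guaranteeing at least one
  witness; the bag label is the OR of the latent node labels. These
  latent labels are retained in the patient record
  (`node_latent_labels`) solely so that tests and reports can verify
  that attention concentrates on witnesses — a real study never sees
  them.

- **Feature views.** Radiomic node features are 32-dimensional
  Gaussians; witness nodes receive a mean shift of 1.5 on features
  1–8, so signal is sparse and the redundancy/LASSO machinery has
  something real to find. The deep view is a fixed random projection
  of the radiomic view passed through `tanh` plus noise (64
  dimensions), giving a correlated-but-distinct second view, as a
  frozen CNN embedding would be. Tumor-level features get an effect of
  0.8 for positive patients.

- **Clinical covariates.** Age ≥ 65, sex, tumor site (upper / middle /
  lower), T stage and tumor length are drawn to match realistic
  marginals and then tilted by a logistic model on the true label
  (coefficients: age 0.6, male 0.3, site 0/0.4/0.7, T stage 0.8,
  length 0.7). The tilt was calibrated so the Clinical sub-model is
  informative but clearly weaker than the imaging models.

- **Survival.** Event times are Weibull proportional hazards (shape
  1.2, scale 60 months): node-positive status multiplies the hazard by
  1.8, and POAT (assigned at random to half the cohort) multiplies it
  by 0.45 *only in truly node-positive patients*. This is the key
  generative fact the final analysis must recover: adjuvant therapy
  helps only the high-risk group. Censoring is uniform administrative
  up to 150 months.

All generation is wrapped in an internal `with_seed()` so the user's
global RNG state is never disturbed, and per-stage seeds are derived
deterministically from one master seed.

# Imaging and radiomics numerics

The imaging module operates on small phantom volumes (`ct_volume`)
with explicit voxel spacing. Choices worth recording:

- **Resampling** is trilinear to a 1 × 1 × 5 mm grid; the implementation
  is exact for constant and linear intensity fields, which the tests
  assert to 1e-8.
- **Windowing** uses the mediastinal window (width 350, level 40 HU),
  mapping to [0, 1] with clipping; background outside the dilated mask
  is set to 0.
- **Discretization** uses a fixed bin width of 25 HU re-anchored at the
  ROI minimum, the standard way to keep bin edges comparable across
  ROIs without fixing the number of levels.
- **Texture matrices**: GLCM is symmetric (counts plus transpose) and
  averaged over four in-plane offsets; GLRLM uses run-length encoding
  along four directions; GLSZM uses 8-connected flood fill, so
  diagonally touching cells merge into one zone; GLDM counts
  equal-level in-plane neighbours. In-plane matrices are accumulated
  across slices rather than computed in 3-D, because the slice spacing
  is several times the in-plane spacing.
- **Shape** features come from a marching-tetrahedra surface extracted
  at the 0.5 level of a 3 × 3 × 3 box-smoothed binary mask with linear
  vertex interpolation. On a radius-10 sphere this yields sphericity
  1.013 — about a 1 % overestimate, well inside the 5 % tolerance the
  tests enforce, and far better than voxel-face surface area, which
  overestimates by ~50 %.

The deep-feature extractor exported for phantoms is a deterministic
frozen random projection ("stub CNN"): a fixed-seed linear map plus
`tanh`. It satisfies the same contract a real network embedding would
(fixed 512-d output, determinism, bounded range) without shipping
weights.

# The attention-MIL network

The network is intentionally small and written in base R with manual
backpropagation, because the pooling mechanism *is* the scientific
claim and must be fully auditable:

- embedding: linear (input → 32) → ReLU → dropout;
- attention: two-layer `tanh` gate (hidden 32) → softmax within bag;
- bag embedding: attention-weighted sum; head: sigmoid.

Training uses focal loss (α = 0.25, γ = 2) to damp the easy majority
bags, an L1 penalty (1e-5) on the embedding weights, Adam
(lr 1e-4, weight decay 1e-6), batches of 32 bags, up to 200 epochs
with early stopping (patience 20) on a 15 % label-stratified
validation split; the returned parameters are the best-validation
snapshot. Bags are processed as grouped instance matrices, which is
algebraically identical to pad-and-mask batching but allocation-free.

Key invariants, all covered by tests: attention weights form a
probability distribution per bag; bag outputs are permutation
invariant; k identical instances share weight 1/k without changing the
bag probability; the analytic gradient matches finite differences;
training is bit-reproducible given the config seed.

# Sub-models, stacking and leakage control

The five base models are MILDL and MILRad (attention-MIL on the deep
and radiomic node views), TumorDL and TumorRad (RBF-SVMs on tumor-level
views, grid-tuned by internal CV), and Clinical (SVM on the encoded
covariates); LLNRad (an SVM on the radiomically largest node only) is
kept as the conventional-practice baseline.

The stacking layer is a logistic meta-model over the five base-model
probabilities. Its meta-feature matrix must be **out-of-fold**: each
patient's base-model scores come from fold models that never saw that
patient. This is enforced structurally — `fit_stacking()` refuses any
matrix that does not carry the `oof` provenance attribute with the
expected columns in the expected order, and `predict_meta()` refuses
permuted or renamed columns. The tests additionally refit a fold model
from scratch and verify the out-of-fold rows match exactly.

# Evaluation and survival analysis

AUC is computed as the Mann–Whitney statistic with ties at 0.5;
confidence intervals use DeLong's structural-components variance.
Operating cutoffs are chosen by maximizing the Youden index on the
*training* scores and then applied unchanged to validation — reported
sensitivity/specificity are therefore honest. Decision-curve analysis
reports net benefit over a threshold grid with the treat-all and
treat-none references; tests pin it to its closed-form anchors (e.g.
treat-all net benefit `prev − (1 − prev) · t/(1 − t)`).

For survival, patients are dichotomized at a stacking-score cutoff of
0.53. The package provides Kaplan–Meier curves with log-rank tests,
Cox models (Breslow ties by default, Efron optional, Wald CIs, an
events-per-term warning, and a rank-deficiency check), and
`poat_benefit_analysis()`, which contrasts treated versus untreated
patients *within each risk group*. On the synthetic cohort this
recovers the generative truth: the POAT hazard ratio in the high-risk
group is well below 1 with a CI excluding 1, while the low-risk CI
spans 1.

# Problem sizes and runtime

The defaults are sized for a single CPU core: pipelines of 100–300
patients run in roughly 1–2 minutes; the 800-patient survival run used
by the acceptance script takes about 5 minutes. An attention-MIL model
needs on the order of 200 training bags to reliably separate bags
*and* rank witness nodes (held-out bag AUC ≈ 0.95+, attention AUC ≈
0.9+ at that scale); below ~120 bags the network undertrains at the
default learning rate.

```{r example}
library(nodebag)
cfg <- pipeline_config(cohort = cohort_config(n_patients = 300, seed = 7),
                       seed = 7)
report <- run_pipeline(cfg)
print(report)
```

# Limitations

- The cohort is synthetic; absolute AUCs reflect the generator's
  separability, not clinical performance.
- The deep view is a frozen random projection, not a trained CNN; it
  stands in for an embedding contract only.
- The radiomics engine implements a compact, test-anchored subset of
  the usual feature families rather than a full standard library.
- Survival uses Wald intervals and proportional hazards throughout; no
  competing risks or time-varying effects.
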