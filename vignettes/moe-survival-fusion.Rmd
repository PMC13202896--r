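---
title: "Attention-based mixture-of-experts fusion for survival prognosis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based mixture-of-experts fusion for survival prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moesurv)
```

## The model

`moesurv` models patient-level time-to-event risk from heterogeneous
"expert groups" of tokens. A group is any per-patient token sequence a
modality-specific encoder can produce: PET or CT axial-slice embeddings,
per-lesion radiomic feature vectors, or clinical-report sentence embeddings.
The canonical configuration uses seven groups (semantic and morphology
vision embeddings for PET and CT, radiomics for PET and CT, and text), all
projected by a per-group single-layer affine map to a shared embedding
dimension.

Fusion proceeds in two symmetric stages.

**Intra-group aggregation.** Each group's tokens
$X^{(g)} = \{x_i^{(g)}\}_{i=1}^{n_g}$ pass through a lightweight Transformer
encoder (multi-head self-attention and a ReLU feed-forward block, each with
a residual connection) giving contextualized tokens $h_i^{(g)}$. A learned
query $q^{(g)}$ pools them:

$$\alpha_i^{(g)} = \frac{\exp(q^{(g)\top} h_i^{(g)})}
  {\sum_j \exp(q^{(g)\top} h_j^{(g)})},
  \qquad z^{(g)} = \sum_i \alpha_i^{(g)} h_i^{(g)} .$$

**Inter-group mixture with gating.** The pooled vectors are refined by a
cross-group Transformer, $\tilde Z = E_\mathrm{inter}(Z)$, scored by a
gating MLP that consumes the refined vectors jointly, and normalized on the
simplex:

$$\pi_g = \frac{\exp(s_g)}{\sum_k \exp(s_k)}, \qquad
  u = \sum_g \pi_g \tilde z^{(g)} .$$

A linear head maps the patient embedding to a scalar risk, $r = w^\top u + b$.
Two endpoint models (progression-free and overall survival) share the
architecture but have fully disjoint parameters, each trained only on its
own endpoint with the negative Cox partial log-likelihood
(Breslow convention for ties, max-subtraction for numerical stability):

$$\mathcal{L} = -\sum_{i:\,\delta_i=1}
  \Big[ r_i - \log \sum_{j:\,t_j \ge t_i} e^{r_j} \Big].$$

Because $\alpha$ and $\pi$ are probability vectors produced on every forward
pass, they double as the interpretability surface: attention rollout turns
the per-layer attention matrices into token (slice/sentence) importances,
and the gating weights quantify each expert group's contribution per patient
and, averaged, per cohort.

## Parameters that matter

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `embed_dim` | 128 | shared embedding width; tests and desk-scale studies use 8-32 |
| `intra_layers` x `n_heads` | 2 x 4 | intra-group encoder depth/heads |
| `inter_layers` | 1 | cross-group encoder depth |
| `gate_hidden` | 32 | gating MLP width |
| `lr` | 1e-3 | Adam step size |
| `batch_size` | 64 | Cox likelihood is computed within each minibatch |
| `val_fraction` / `patience` | 0.2 / 5 | early stopping on held-out loss |
| `weight_decay` | 1e-4 | decoupled (AdamW-style) shrinkage per step |
| VOI `frac` | 0.41 | lesion threshold as a fraction of SUVmax |
| rollout `residual` | 0.5 | residual mixing weight in attention rollout |

Times are in months throughout; SUV is unitless (body-weight normalized,
tissue density 1 g/mL); TMTV is cm^3.

## Numerical and design choices

* **No autodiff dependency.** The forward and backward passes of every
  block are written directly in vectorized base R and verified against
  central-difference numerical gradients in the test suite (agreement
  ~1e-9 on the full stack).
* **Near-identity residual initialization.** The output matrices of both
  residual branches (`Wo`, `W2`) start at one tenth the usual scale, so each
  Transformer block is close to the identity at initialization. This keeps
  the un-normalized (LayerNorm-free) stack stable and keeps each refined
  group vector close to its own pooled vector early in training, which is
  what makes the gating weights attributable to their groups: without it the
  cross-group attention redistributes a single informative group's signal
  across all refined vectors before the gate ever differentiates, and the
  mixture weights lose their meaning.
* **Variable token counts** are handled by processing patients one at a
  time (token matrices are ragged across patients), so no padding or
  attention masking is needed anywhere.
* **Ties** are Breslow everywhere: in the training loss, in
  `cox_regression()` (via `survival::coxph(ties = "breslow")`) and in the
  Breslow baseline hazard used to convert risk scores into absolute
  survival probabilities for calibration, decision curves and nomograms.
* **Gate input.** Whether the gate should see the refined vectors jointly
  or one at a time is an open design point; the joint (flattened) form is
  used, since a per-group gate cannot model "this expert is informative
  *relative to* the others".
* **R-signature scale.** The raw linear risk score is used for
  stratification and as a Cox covariate; any monotone display rescaling is
  left to the caller.
* **Imaging conventions.** Arrays are `(z, y, x)` with 0-based voxel
  coordinates and `world = origin + index * spacing`. VOI growth uses
  26-connectivity, matching common lesion-segmentation tools. CT is clipped
  to [-1000, 1000] HU and PET to [0, 30] SUV before [0, 1] scaling (the
  PET scaling applies inside a robust body mask: voxels above the 5th
  percentile of nonzero SUV); all three are configurable. The
  percent-of-SUVmax threshold is applied per lesion (grown from the seed
  region's maximum), not globally. NMI registration uses a 32-bin joint
  histogram and seeded multi-start coordinate descent, with translations
  bounded to half the field of view and rotations to +/-15 degrees.
* **Time-dependent ROC** uses the cumulative-case / dynamic-control IPCW
  estimator with Kaplan-Meier censoring weights; with zero censoring it
  reduces exactly to the binary AUC (asserted in tests). Bootstrap CIs are
  seeded percentile intervals with 1000 replicates by default.
* **Decision curves** use a 36-month default horizon, near the median
  follow-up of the clinical setting the package targets; patients censored
  before the horizon are excluded and counted.
* **Degenerate inputs.** Radiomics on a constant region returns variance,
  skewness, kurtosis and entropies of 0 and GLCM angular second moment 1;
  a single-pixel mask yields all-zero co-occurrence features. Zero events
  make the Cox loss 0 with a warning. Empty risk-group or empty-class
  inputs to stratification/ROC are errors, not silent NAs.

## The synthetic cohort generator

With no public imaging/EHR cohort to ship, `generate_cohort()` defines the
study conditions every downstream stage is tested under:

* latent risk $r \sim N(0,1)$ per patient; each endpoint uses
  $(r + 0.5\,\varepsilon)/\sqrt{1.25}$ with independent
  $\varepsilon$, so PFS and OS are related but distinct targets;
* event times are exponential proportional hazards,
  $h(t) = h_0 \exp(\sum_j \beta_j x_j + \beta_r \cdot \text{risk})$, with
  $h_0 = 0.02$ per month (median ~35 months at the baseline, matching the
  follow-up scale of the target setting) and OS at 0.6 times the PFS
  baseline hazard;
* binary covariates (elevated beta2-microglobulin, WBC, high Ki-67) are
  Bernoulli(1/2) with log-hazard coefficients 0.4/0.3/0.5; the continuous
  metabolic-burden covariate enters as standardized log-TLG with
  coefficient 0.3;
* censoring is an independent uniform time on $[0, T_\mathrm{adm}]$ with
  $T_\mathrm{adm}$ calibrated by root finding so the expected censored
  fraction hits `censor_rate` (default 0.3);
* group `g`'s tokens are isotropic Gaussian noise shifted by
  `group_signal[g]` $\cdot\, r$ along a fixed unit direction drawn once per
  group (default signal 0.5 in every group).

What this emulates: multimodal token groups whose informativeness is
controllable per group, proportional-hazards outcomes with realistic
censoring, and covariates with known hazard ratios for recovery tests. What
it does not emulate: scanner noise and batch effects, anatomical structure,
correlated token noise, informative censoring, or foundation-model embedding
geometry. Passing tests therefore demonstrate the *mechanics* (losses,
simplex constraints, attribution, recovery of planted signal), not clinical
performance on real data. One consequence of the design worth knowing: the
signal directions are part of a cohort draw, so a model transfers to new
patients drawn with the same directions (the supported held-out protocol)
but not to a cohort generated under a different seed.

## Problem sizes

The shipped tests and the acceptance script run at desk scale by choice:
oracle comparisons at $n \le 30$, smoke cohorts of 60 patients at embedding
dimension 16, training studies at $n = 400$ with 32-dimensional tokens and
a 16-dimensional fusion model, and Cox parameter recovery at $n = 1000$.
Scaling up is a matter of configuration, not code.

## Known limitations

* Foundation vision/language encoders are out of scope; the shipped
  `encoder_plugin` stand-ins are seeded random projections of deterministic
  input statistics, which preserve the architecture but not the semantics
  of pretrained embeddings.
* The multi-category (Mahalanobis) SMD convention varies across published
  tables; `smd_multicat()` implements the standard formula and is excluded
  from the verified table-one surface.
* Registration is rigid (optionally axis-scaled); deformable registration,
  scatter/attenuation modelling and DICOM parsing are out of scope.
* `harrell_cindex()` enumerates pairs in O(n^2) memory; it is intended for
  cohort-scale (thousands), not biobank-scale, inputs.
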