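# moesurv

Interpretable multimodal survival prognosis with an attention-based
mixture-of-experts (MoE) fusion network, in pure R.

## Who this is for

Researchers modeling time-to-event outcomes (progression-free and overall
survival) from heterogeneous patient data — PET/CT imaging, radiomic
features, and clinical-report text — who want a *single* trainable model
that fuses the modalities **and** explains, per patient, which modality
drove the risk estimate. The package targets desk-scale methodological
work: everything (including a synthetic cohort generator with known
proportional-hazards ground truth) runs offline on one CPU with no
pretrained weights or external data.

## The model

Each patient contributes `G` expert token groups
`X⁽ᵍ⁾ = {xᵢ⁽ᵍ⁾}`, i = 1..n_g (image-slice embeddings, per-lesion radiomic
vectors, sentence embeddings), projected by a per-group affine layer to a
shared dimension. Fusion is two-stage:

1. **Intra-group aggregation** — a lightweight Transformer encoder
   contextualizes each group's tokens into `hᵢ⁽ᵍ⁾`; a learned query `q⁽ᵍ⁾`
   pools them by attention:

       αᵢ⁽ᵍ⁾ = softmaxᵢ( q⁽ᵍ⁾ᵀ hᵢ⁽ᵍ⁾ ),   z⁽ᵍ⁾ = Σᵢ αᵢ⁽ᵍ⁾ hᵢ⁽ᵍ⁾

2. **Inter-group mixture with gating** — a cross-group Transformer refines
   the pooled vectors (`z̃⁽ᵍ⁾`), a gating MLP scores them, and softmax
   weights mix them into the patient embedding:

       π_g = softmax_g(s_g),   u = Σ_g π_g z̃⁽ᵍ⁾,   risk r = wᵀu + b

Separate PFS and OS heads (disjoint parameters, same architecture) train
on the negative Cox partial log-likelihood with Breslow ties:

       L = − Σ_{i: δᵢ=1} [ rᵢ − log Σ_{tⱼ ≥ tᵢ} exp(rⱼ) ]

All forward/backward passes are hand-written vectorized R, verified against
numerical gradients in the test suite. The attention weights `α`, the gate
weights `π` (via attention rollout and cohort averaging), and a modality
ablation harness form the interpretability surface. Around the model sits a
full evaluation stack — Harrell's C-index with bootstrap CI, IPCW
time-dependent ROC, Kaplan–Meier/log-rank, Breslow-baseline calibration and
decision curves, nomogram point mapping — plus PET quantification (SUV
conversion, 41%-of-SUVmax VOI segmentation, SUVmax/TMTV/TLG), NMI rigid
registration, and table-one cohort-balance statistics (binary SMD,
Yates-corrected χ², Welch t, Mann–Whitney U).

## Worked example

```r
library(moesurv)

# 1. simulate a 200-patient multimodal cohort with known PH ground truth
coh <- generate_cohort(cohort_config(200, embed_dim = 32, beta_r = 1.5, seed = 11))

# 2. train the PFS head
arch <- moe_config(n_groups = 7, embed_dim = 16, n_heads = 2,
                   intra_layers = 1, gate_hidden = 16, input_dims = 32)
m <- train_task(coh, "PFS", arch = arch,
                train = train_config(epochs = 10, batch_size = 100, seed = 2))

# 3. evaluate on the held-out split
rec <- cohort_records(coh, "PFS"); va <- m$split$validation
risks <- predict_cohort(m, coh, va)
harrell_cindex(risks, list(time = rec$time[va], event = rec$event[va]),
               n_boot = 200, seed = 3)
td_roc(risks, list(time = rec$time[va], event = rec$event[va]), 24)

# 4. which modalities carried the decision?
gating_contributions(m, coh)

# 5. PET quantification on a digital phantom
ph <- generate_phantom(c(24, 24, 24),
                       list(list(center = c(12, 12, 12), radius = 8, peak = 12)))
metabolic_metrics(ph$pet, threshold_voi(ph$pet))
```

Output:

```
validation C-index 0.744 (95% CI 0.648-0.828)
AUC(24 months) = 0.888
Mean gating weights per group:
  vision_semantic_pet    vision_semantic_ct vision_morphology_pet
               0.2644                0.1262                0.0926
 vision_morphology_ct         radiomics_pet          radiomics_ct
               0.0763                0.1368                0.1986
                 text
               0.1052
Modality aggregates:
    CT    EHR    PET
0.4011 0.1052 0.4938
SUVmax 12.000  TMTV 0.744 cm^3  TLG 5.441 (SUVmean 7.313, 93 voxels)
```

The C-index says the trained head ranks held-out patients' progression
times well above chance; the gating table attributes roughly half of the
fused decision to PET-derived groups on this cohort; and the phantom
metrics are the three standard PET burden measures computed from the
41%-of-SUVmax lesion mask.

A thin command-line wrapper ships in `inst/cli/moesurv`
(`simulate`, `run-all`, `tableone`, `evaluate` subcommands), and
`run_pipeline()` executes simulate → train (PFS, OS) → evaluate → interpret
end-to-end with a checksummed manifest.

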