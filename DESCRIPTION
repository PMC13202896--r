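Package: moesurv
Title: Attention-Based Mixture-of-Experts Fusion for Multimodal Survival
    Prognosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interpretable multimodal prognostic modeling for time-to-event
    endpoints, built around an attention-based mixture-of-experts fusion
    network. Expert token groups (PET and CT slice embeddings, radiomic
    feature vectors, clinical-report sentences) are encoded by lightweight
    Transformer blocks, pooled with learned-query attention, fused across
    groups through softmax gating, and mapped to scalar risk scores trained
    with the negative Cox partial log-likelihood for separate
    progression-free and overall survival heads. Includes PET metabolic
    quantification (SUV conversion, 41 percent-of-SUVmax volumes of
    interest, SUVmax/TMTV/TLG), normalized-mutual-information rigid
    registration, attention-rollout and gating-weight interpretability,
    a synthetic cohort generator with proportional-hazards ground truth,
    and a survival-evaluation stack (Harrell's C-index, time-dependent ROC,
    Kaplan-Meier and log-rank, Cox regression, calibration, decision-curve
    analysis, nomogram point mapping) plus table-one cohort-balance
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    RNifti,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
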