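Package: neopain
Title: Neuro-Symbolic Multimodal Assessment of Neonatal Pain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for interpretable neonatal pain assessment
    from multimodal NICU episodes (cry audio, physiological time series,
    facial action channels, context metadata). Raw signals are mapped to
    twelve clinical concepts with gestational-age-stratified thresholds,
    fused over a concept graph with missing-modality masking, and scored by
    an evidential Dirichlet head that abstains under high epistemic
    uncertainty. An 18-rule symbolic engine with three-tier conflict
    resolution produces templated explanations and recommendations,
    including a dedicated protocol for ventilated infants. The package also
    provides per-infant few-shot personalization, a federated-averaging
    simulator with differentially private local updates and Renyi privacy
    accounting, a synthetic episode generator with known ground truth, and
    ordinal evaluation metrics (quadratic weighted kappa, calibration,
    selective accuracy under abstention).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
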