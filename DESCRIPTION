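Package: molpert
Title: Single-Subject Molecular Network Perturbation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds covariate-adjusted partial-correlation reference networks
    from regional molecular-imaging data (e.g. FDOPA PET SUVr tables), derives
    per-subject edge-wise deviation z-matrices by single-subject network
    perturbation, and summarises them as subject-level (SED) and regional
    (RED) extreme-deviation metrics. Includes the downstream analysis battery:
    nonparametric group comparisons with FDR correction and effect sizes,
    linear support-vector-machine classification with permutation testing and
    SMOTE class balancing, connectome fingerprinting across timepoints, and
    reference-network stability resampling. Ships a synthetic cohort
    generator emulating control, patient and longitudinal designs so the full
    pipeline is testable without restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071
Suggests:
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
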