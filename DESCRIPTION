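Package: denoisebench
Title: Benchmarking Data-Driven Physiological Denoising for Fast-TR
    Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare data-driven physiological denoising methods
    (global-signal regression, white-matter/CSF regression, anatomical and
    temporal CompCor, and an ICA-based motion/physiology classifier) on
    fast-TR resting-state BOLD fMRI. Includes a multi-subject synthetic
    cohort generator with ground-truth component bookkeeping, minimal
    preprocessing (discrete-cosine high-pass, Gaussian smoothing, framewise
    displacement, temporal SNR), band-resolved spectral-power accounting
    around subject-specific cardiac and respiratory frequencies,
    functional-connectivity metrics (template-based rotation maps, ROI
    correlation matrices, functional-connectivity contrast, age-partition
    modularity), linear mixed-model group statistics with
    Benjamini-Hochberg correction, and a downsampling experiment probing
    the aliasing of physiological signals at conventional sampling rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    nlme,
    stats,
    utils
Suggests:
    lmerTest,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
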