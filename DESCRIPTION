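Package: lutphysio
Title: Analysis of Lower Urinary Tract Neurophysiology Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of simultaneous fiber-photometry/cystometry,
    optogenetics/external-urethral-sphincter electromyography, and micturition
    video thermography experiments in rodents. Provides motion-corrected
    delta-F/F0 calcium signals with isosbestic (405 nm) subtraction, detection
    and dP/dt alignment of voiding and non-voiding bladder contractions,
    peri-event matrices with shuffle-null controls, EMG total-power epoch
    statistics with per-animal response rates, and thermal-image void-spot
    quantification with template-based area calibration. A synthetic-session
    generator with full ground truth makes every analysis stage verifiable by
    ground-truth recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    EBImage,
    png,
    tiff
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
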