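Package: relaxomap
Title: Voxel-Wise MR Relaxometry Mapping and Contrast-Agent Calibration
Version: 0.1.0
Authors@R: person("relaxomap", "maintainers", email = "maintainers@relaxomap.org",
    role = c("aut", "cre"))
Description: Quantitative magnetic-resonance relaxometry pipeline for
    characterizing iron-oxide nanoparticle contrast agents. Provides forward
    mono- and bi-exponential transverse decay and inversion-recovery models,
    synthetic multi-echo phantom and injected-tissue volume generators with
    known ground truth, per-voxel Levenberg-Marquardt curve fitting, AIC/BIC
    model-selection and binary dual-component maps, relaxivity calibration
    against iron concentration with a 3-sigma limit of detection, NMRD
    (nuclear magnetic relaxation dispersion) profile assembly, ROI
    enhancement time courses, and organ-iron normalization. Volumes are read
    and written as uncompressed NIfTI-1 with a plain-text echo-time sidecar.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
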