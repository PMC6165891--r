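Package: lesionpipe
Title: Harmonization, Correction and Load Analysis of Stroke Lesion Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quality-controlled processing pipeline for T1-weighted MRI and
    binary stroke lesion masks. Harmonizes per-subject NIfTI files to the
    radiological storage convention and a canonical axis ordering, flags
    subjects whose files disagree, removes healthy white-matter-intensity
    voxels from manually traced lesion masks, registers subjects to a
    region-of-interest template space to compute percent lesion load, and
    renders tri-planar HTML review galleries whose pass/fail records gate
    downstream stages. Ships a deterministic synthetic head-phantom generator
    (three-tissue brain, skull shell, intensity-lowered lesion, simulated
    tracer variants, template and ROI sets) so every stage is testable
    without patient data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    png,
    grDevices,
    stats,
    utils
Suggests:
    oro.nifti,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
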