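Package: socialfish
Title: Social Preference Behaviour and Whole-Brain c-fos Activity Mapping in Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for quantifying social preference
    in juvenile zebrafish and mapping the associated whole-brain c-fos activity.
    Covers behavioural video tracking (crop, background subtraction,
    thresholding, centroid/orientation/motion extraction), the visual
    preference index (VPI) with pro-/anti-social classification, percent time
    moving and freezing-bout detection, one-minute binned time courses,
    histogram-based background normalization of registered fluorescence
    volumes, group-average and normalized difference maps, 3D-mask region
    activation percentages, and non-parametric (Mann-Whitney U) group
    comparisons. A companion synthetic-data module generates ground-truthed
    behavioural videos and brain-volume cohorts so every stage can be validated
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    tiff,
    png,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
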