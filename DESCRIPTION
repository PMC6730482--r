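Package: tractmargin
Title: White-Matter Path-Length Maps and Anisotropic Radiotherapy Margins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Converts diffusion-MRI tractography streamlines into white-matter
    path-length (WMPL) maps, in which every voxel carries the shortest
    along-streamline distance (in mm) back to a target region of interest such
    as a gross tumor volume, and turns those maps into anisotropic clinical
    target volumes for radiotherapy planning by expansion-path-length
    thresholding, union with the tumor volume, exact metric dilation and brain
    clipping. Includes TrackVis TRK and NIfTI-1 input/output with coordinate
    frame reconciliation across differing voxel orders, streamline targeting
    and Cluster Confidence Index outlier filtering, a minimal deterministic
    fiber tracker, a synthetic phantom generator with analytically known path
    lengths, and an end-to-end pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
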