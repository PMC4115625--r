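Package: voxlight
Title: Searchlight Decoding and Permutation Inference for Block-Design fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the analysis of block-design functional MRI voice
    localizer experiments with both univariate and multivariate tracks: a
    synthetic cohort generator with plantable region effects whose mean
    amplitude and multivoxel pattern reliability are controlled
    independently, per-block general linear model estimation yielding
    beta-series classification exemplars, whole-brain searchlight decoding
    with a linear support vector machine under leave-one-out
    cross-validation, and nonparametric second-level inference with
    maximum-statistic permutation family-wise error correction, conjunction
    masking, cluster extraction and Cohen's d effect sizes. An end-to-end
    pipeline reproduces the methodological dissociation in which group
    differences are detectable by pattern decoding but not by the
    univariate contrast.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
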