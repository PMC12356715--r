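Package: qmriAtlas
Title: Normative Quantitative MRI Brain Atlases and Voxel-Wise Deviation Mapping
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds voxel-wise normative reference atlases (mean and standard
    deviation volumes) for quantitative MRI parameter maps (myelin volume
    fraction, proton density, R1 and R2 relaxation rates), derives per-region
    +/- 3 SD reference ranges, and detects single-subject deviations through
    difference and z-score maps. Includes a parcellated digital brain phantom
    for simulating multi-subject cohorts with known ground truth (including
    focal demyelinating lesions), a simplified multi-dynamic multi-echo signal
    model with a four-compartment myelin volume fraction solver, a spatial
    pipeline (bias-field correction, co-registration, degree-4 B-spline
    reslicing, template normalization), and the validation statistics used for
    normative-atlas studies (Mann-Whitney group comparisons, age correlations
    with multiplicity correction, masked image cross-correlation, tissue
    segmentation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Rcpp, RNifti, jsonlite, yaml, mclust
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'utils.R'
    'atlas.R'
    'deviation.R'
    'mdme.R'
    'nifti-io.R'
    'phantom.R'
    'stats.R'
    'roi.R'
    'spatial.R'
    'pipeline.R'
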