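Package: ivtlab
Title: Infarct Border-Zone Substrate Modeling and In-Silico Ventricular
    Tachycardia Induction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating infarct-related ventricular tachycardia
    on image-derived tissue models. Builds labeled anisotropic hexahedral
    tissue grids from delayed-enhancement MRI-like intensity volumes
    (standard-deviation scar/border-zone classification, intensity-ranked
    patchy fibrosis, rule-based fiber fields, transmural layers), solves
    the anisotropic monodomain reaction-diffusion equation with the ten
    Tusscher-Panfilov human ventricular membrane model (including
    border-zone ionic remodeling) and the MacCannell fibroblast model,
    runs programmed-electrical-stimulation inducibility protocols with
    reentry detection, and computes forward electrocardiograms through a
    torso volume conductor.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
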