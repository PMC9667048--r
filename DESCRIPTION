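Package: petdx
Title: Differential Diagnosis of Dementia Syndromes from FDG-PET Metabolic Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated differential diagnosis of common dementia syndromes
    (Alzheimer's disease, dementia with Lewy bodies, frontotemporal dementia)
    versus normal controls from FDG-PET brain volumes. Implements scaled
    subprofile model principal component analysis (SSM/PCA) pattern derivation
    with single-case topographic profile rating, atlas-based regional uptake
    features, a repeated stratified multi-class linear support-vector-machine
    ensemble with majority voting and leakage control, confusion-matrix
    performance metrics with one-vs-all ROC/AUC, and model explanation via
    neighborhood component analysis feature weights and Shapley-value regional
    importance maps. Ships a synthetic cohort generator with planted
    class-specific hypometabolic topographies so the whole pipeline is testable
    end to end without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
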