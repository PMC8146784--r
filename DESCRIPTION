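Package: SpectraVote
Title: Majority-Voting Ensemble Classification of Vis/NIR and SWIR
    Reflectance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection of internal produce defects from external
    visible/near-infrared and short-wavelength-infrared reflectance
    spectra. Provides spectral preprocessing (absorbance conversion,
    polynomial detrending, median smoothing), wrapper-based effective
    wavelength selection driven by a cultural algorithm, feed-forward
    neural classifiers tuned by imperialist-competitive and
    harmony-search metaheuristics, k-nearest-neighbour and stepwise
    linear discriminant classifiers, a majority-voting ensemble, a
    repeated stratified-split evaluation harness with pooled confusion
    matrices, per-class metrics, ROC/AUC and paired t-test comparison,
    and a seeded synthetic spectra generator with planted
    class-discriminative wavelength bands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC,
    MASS,
    class
Config/testthat/edition: 3
RoxygenNote: 7.3.3
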