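Package: psmaquant
Title: Automated Lesion Detection and Uptake Quantification for PSMA PET/CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of prostate-specific membrane antigen (PSMA)
    PET/CT given a co-registered organ label map: reference-organ uptake
    quantification (interquartile-range mean in the thoracic aorta, dominant
    mode of a two-component Gaussian mixture in the liver), multi-scale blob
    detection of candidate lesions per tissue compartment with suppression of
    physiological uptake in liver, kidneys and bladder, fast-marching lesion
    pre-segmentation, and SUVmax/SUVpeak/SUVmean/volume quantification.
    Includes the evaluation statistics used to characterise such pipelines
    (Dice, matched detection sensitivity with Wilson intervals, Pearson
    correlation, inter-method standard deviation, intraclass correlation
    ICC(2,1)) and a synthetic trunk phantom generator that supplies
    co-registered SUV volumes, organ label maps and lesion ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
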