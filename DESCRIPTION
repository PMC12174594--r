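Package: octeval
Title: Quantitative Structural Evaluation of Predicted Retinal OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess predicted (image-to-image translated) post-therapeutic
    retinal OCT B-scans against real follow-up scans in eyes with macular edema.
    Provides a synthetic paired pre/post B-scan phantom generator with known
    layered anatomy and fluid lesions; mask-derived anatomical measurement
    (central and maximal retinal thickness, subretinal and intraretinal fluid
    areas); a classical, training-free segmentation backend for the phantoms;
    per-class segmentation quality metrics (recall, precision, IOU, Dice);
    treatment-response trend classification with a relative-change rule and
    exact binomial (Clopper-Pearson) confidence intervals; and a
    normality-gated paired-comparison plus Bland-Altman agreement protocol,
    assembled into a reproducible evaluation report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
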