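Package: screenbias
Title: Quantification and Correction of Structural Biases in Pooled CRISPR-Cas9 Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify and correct the two structural biases of pooled
    CRISPR-Cas9 dropout screens: copy-number amplification bias and chromosome-arm
    proximity bias. Implements an arm-median alignment correction for multi-screen
    gene-effect matrices and a per-arm unexpressed-gene centering correction for
    single screens, together with an evaluation suite (amplified-unexpressed recall
    AURC, copy-number-binned residual difference, Brunner-Munzel per-arm proximity
    probabilities with TP53 stratification, essential-gene AUROC/AUPRC/NNMD, recall
    at fixed FDR, oncogene-addiction ROC, and a differential-dependency biomarker
    scan) and a seeded synthetic screen generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
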