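Package: radstab
Title: Repeatability and Reproducibility Analysis of Radiomic Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to study the stability of quantitative image features
    ("radiomics") across scanners, acquisition protocols and repeated scans.
    Extracts first-order and gray-level texture features (GLCM, GLRLM, GLSZM,
    NGTDM, GLDM) from 3D volumes after isotropic resampling, Laplacian-of-
    Gaussian and undecimated 3D wavelet filtering; scores per-feature
    stability with the two-way mixed-effects consistency intraclass
    correlation ICC(3,1); filters features collinear with tumor volume by
    Spearman correlation; and selects the set of features that are both
    repeatable and reproducible across designed multi-scanner multi-protocol
    experiments. Includes a synthetic-data module that generates phantom
    image volumes and long-format feature tables with known
    variance-component ground truth, so the full pipeline is testable end to
    end.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
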