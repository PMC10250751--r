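Package: pdxforge
Title: Genomic and Pharmacological Credentialing of Patient-Derived Xenograft Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative characterization of prostate-cancer patient-derived
    xenograft (PDX) panels: somatic variant post-filtering and tumor mutational
    burden, allele-specific copy-number reconstruction from SNP LRR/BAF profiles
    with joint ploidy and normal-cell contamination estimation (circular binary
    segmentation plus a lattice fit), coverage-based focal amplification and
    homozygous-deletion calling, STR-profile identity authentication, in-vivo
    tumor-growth response metrics with mRECIST classification, and TPM-based
    expression clustering and signature scoring. Every stage is driven by
    forward simulators with known ground truth, so the whole pipeline is
    verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
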