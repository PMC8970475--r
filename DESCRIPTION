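Package: codonfp
Title: Codon Usage Bias Fingerprints in Tissue- and Disease-Specific Gene Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes within-amino-acid-family codon usage (CU) values for
    coding sequences, detects unused ("zero") and extremely biased codons,
    builds gene-by-codon fingerprint matrices with Euclidean complete-linkage
    hierarchical clustering, prioritizes differentially used codons between
    cohorts (disease-causing vs non-disease-causing, tissues, species) with
    two-tailed rank-sum tests and Spearman correlations, and maps pathogenic
    coding substitutions onto their reference codons ("mapping-on-codons").
    Includes a seeded generator of synthetic coding-sequence cohorts with
    controlled codon-preference structure and variant lists with known
    per-codon intensities, so every analysis stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
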