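Package: ptisig
Title: Derivation and Validation of Therapy-Induced Secretome Gene Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to derive an interferon-regulated, therapy-induced tumor
    secretome gene signature from multi-assay evidence (bulk RNA-seq fold
    changes, cytokine antibody-array densitometry, qRT-PCR), and to validate
    signatures by average-CPM scoring and from-scratch preranked gene-set
    enrichment with gene-set permutation FDR. Includes upper-quartile CPM
    normalization, secretome and interferon-regulation annotation filters,
    a seeded multi-omic synthetic data generator with planted signatures,
    and a reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
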