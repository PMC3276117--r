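Package: cnvhaplo
Title: CNV Haplotype and Diplotype Inference from Probabilistic Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates population haplotype frequencies and individual
    diplotypes at copy-number-variable (CNV) loci from noisy,
    probabilistically represented microarray data. Instead of hard calls,
    each individual carries a likelihood over all possible total copy
    numbers (ICN sites), base multisets (SNVC sites) or genotypes (SNP
    sites); an expectation-maximization algorithm with Hardy-Weinberg
    diplotype priors weights every diplotype consistent with the data by
    its likelihood. Includes a Gaussian signal-intensity model, a
    noise-calibrated simulator, and evaluation metrics (total variation
    distance, diplotype accuracy, correction/corruption rates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
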