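Package: sirescan
Title: Paternal-Allele Scanning to Distinguish Sperm Storage from
    Parthenogenesis in SNP-Genotyped Litters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding whether a litter born to an isolated female
    was fathered by stored sperm (long-term sperm storage) or produced
    asexually (facultative parthenogenesis) from biallelic SNP genotypes.
    Reads and filters Structure-format genotype matrices, scans offspring for
    non-maternal alleles at maternal-homozygous loci with a conservative
    all-offspring criterion, classifies the litter's reproductive mode,
    estimates the minimum number of sires from pairwise full-sib versus
    half-sib likelihoods, simulates litters under Mendelian or automictic
    inheritance with a genotyping-error overlay, and predicts double-digest
    RAD fragments from a genome sequence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
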