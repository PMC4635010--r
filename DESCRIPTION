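Package: hmwgs
Title: Characterization of High Molecular Weight Glutenin Subunit Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sequence characterization toolkit for wheat high molecular weight
    glutenin subunit (HMW-GS) genes: open reading frame validation and
    translation, four-domain segmentation (signal peptide, N-terminal,
    central repetitive, C-terminal), tandem repeat-motif decomposition into
    hexapeptide/nonapeptide/tetrapeptide units, cysteine and glutamine
    accounting, average molecular mass deduction with MALDI-TOF concordance,
    pairwise global alignment with SNP/indel calling and
    transition/transversion and codon-effect classification, sequence
    identity matrices, neighbour-joining phylogeny with bootstrap support,
    and a synthetic HMW-GS generator providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
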