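Package: afgpkit
Title: Annotation and Evolutionary Analysis of Antifreeze Glycoprotein
    Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising antifreeze glycoprotein (AFGP) gene
    families in codfishes and other teleosts from nucleotide sequence:
    codon-framed detection of the (Thr-Ala/Pro-Ala)n tripeptide-repeat
    coding tract, classification of genes versus pseudogenes, enumeration
    of trypsin-like polyprotein cleavage sites (single Arg, single Lys,
    Arg-Ala-Ala-Arg), exhaustive digestion into predicted mature isoforms
    with glycosylated average-mass estimation and historical size binning,
    per-position codon-usage tables with bias flags, neighbor-joining gene
    trees from non-repetitive flanking regions with ortholog assignment
    and duplication-order inference, and a ground-truthed simulator of
    repeat-tract and gene-family expansion by slipped-strand mispairing,
    substitution, and whole-gene duplication.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
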