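Package: bsaqtl
Title: Bulked-Segregant QTL-Seq Analysis with Simulated F2 Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for QTL-seq (bulked segregant
    analysis by pooled whole-genome sequencing) in biparental crosses.
    Simulates an F2 population with a planted additive QTL, nitrogen-use
    efficiency phenotypes, extreme-phenotype bulks and pooled allele
    depths; computes per-site SNP-index and sliding-window delta(SNP-index)
    scans with Monte-Carlo confidence thresholds and candidate-interval
    calling; classifies SNP and InDel effects against gene models
    (stop gain/loss, nonsynonymous, splice-proximal, frameshift, promoter);
    designs InDel markers and narrows QTL intervals by substitution
    mapping over recombinants; and reproduces sequencing-summary
    arithmetic for report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    stats,
    utils,
    generics,
    yaml,
    jsonlite,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
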