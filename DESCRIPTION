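Package: linkanchor
Title: Evidence-Based Anchoring of Assembly Scaffolds to Linkage-Group
    Pseudomolecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Places genome-assembly scaffolds into chromosome-scale
    super-scaffolds using concordant evidence from genetic-map marker
    alignments, overhanging long reads, and BAC end pairs. Scaffolds are
    assigned to linkage groups by marker majority, ordered and oriented by
    centimorgan position, and marker-less scaffolds are inserted where
    split long-read alignments indicate adjacency. Builds are materialized
    as AGP v2.1 and stitched FASTA pseudomolecules. Companion quality
    metrics cover Phred arithmetic, k-mer-based consensus quality and
    completeness, k-mer set comparison between assemblies, BAC end-pair
    classification, and N50/NG50 contiguity statistics. A deterministic
    simulator generates truth genomes, fragmented scaffolds, markers,
    junction-spanning reads, and mate pairs so the whole pipeline is
    testable without external aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
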