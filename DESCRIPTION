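Package: halomotif
Title: Palindrome Avoidance, Terminal Repeats and CxxC Census for Halovirus Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for linear dsDNA haloarchaeal virus
    genomes. Counts oligonucleotides, computes Markov-model expected
    frequencies and odds ratios to quantify restriction-site (palindrome)
    avoidance, detects terminal direct repeats (TDRs) of linear virion
    genomes, linearizes integrated proviruses at a chosen terminus, censuses
    CxxC (zinc-finger signature) motif proteins, and estimates pairwise
    whole-genome nucleotide identity by seed-and-chain anchoring with banded
    gap closure. Includes a synthetic-genome generator with motif exclusion,
    planted terminal repeats and annotated coding sequences so every analysis
    stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
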