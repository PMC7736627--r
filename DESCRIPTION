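Package: mitocomp
Title: Comparative Mitogenomics of Sebastiscus Rockfishes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of circular vertebrate
    mitochondrial genomes, built around the three Sebastiscus rockfishes
    (S. tertius, S. albofasciatus, S. marmoratus). Validates gene feature
    tables against the canonical 37-gene vertebrate order; computes base
    composition, A+T content and AT/GC skew for whole genomes, regions and
    codon-position partitions; extracts protein-coding genes under the
    vertebrate mitochondrial code with incomplete-stop handling and computes
    relative synonymous codon usage (RSCU) and amino-acid usage; estimates
    codon-position-partitioned p-distances and Nei-Gojobori (1986) Ka/Ks with
    Jukes-Cantor correction and selection classification; detects tandem
    repeats in the control region; and builds concatenated protein-coding
    supermatrices, TN93 distances, neighbor-joining trees with bootstrap
    support and topology-constraint checks. A seeded synthetic-mitogenome
    generator with a ground-truth ledger makes every stage testable without
    downloading accessions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
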