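Package: AMGsurveyor
Title: Auxiliary Metabolic Gene Surveys of Ocean Virus Metagenomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for cataloging auxiliary metabolic genes (AMGs) carried by
    marine virus populations from assembled metagenomes. Implements contig
    screening and species-rank virus population (vOTU) clustering at 95%
    average nucleotide identity over 80% aligned fraction, permissive and
    conservative AMG curation with a per-gene decision trail (viral-region
    containment, prophage-end evidence from tRNAs and exact inverted/direct
    repeats, and a mobile-element blacklist), greedy gene clustering and
    novelty assessment against published reference AMGs, a genome
    fragmentation mock-community simulator that estimates the conversion
    factor correcting observed AMG-carrying population fractions, KEGG module
    stepwise-completeness mapping of AMG-targeted pathway hot-spots, and
    trimmed-mean population abundances with virus-versus-microbe KO
    enrichment. A seeded synthetic-data generator emulates the statistical
    structure of global-ocean survey inputs so that every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
biocViews: Metagenomics, Microbiome, Sequencing, Annotation, Pathways
Config/testthat/edition: 3
RoxygenNote: 7.3.3
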