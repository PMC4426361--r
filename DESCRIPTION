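Package: mullerf
Title: Comparative Genomic Characterization of Heterochromatic Chromosome Domains
Version: 0.9.0
Authors@R: person("mullerf", "maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for the comparative genomic
    characterization of heterochromatic chromosome domains such as the
    Drosophila Muller F element ("dot" chromosome) against euchromatic
    reference regions.  Provides repeat-landscape scanners (k-mer occurrence
    spectra, dinucleotide-run tabulation, sliding-window transposon density),
    gene-architecture feature extraction with Kruskal-Wallis group comparisons,
    codon-usage-bias statistics (Wright's effective number of codons, the
    codon adaptation index with a self-consistent reference set, and a
    LOESS-based selection-versus-mutational-bias regime call), nearest-neighbor
    DNA melting-temperature metagene profiles, robust multivariate outlier
    detection via the Stahel-Donoho estimator, and synteny/reversal-distance
    analysis (exact Hannenhalli-Pevzner signed reversal distance with scenario
    reconstruction).  A seeded synthetic-data module generates genomes, gene
    models, repeat annotations and ortholog tables with known planted
    structure so that every stage has a recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    IRanges,
    BiocGenerics,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
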