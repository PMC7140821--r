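Package: hapcurate
Title: Curation of Heterozygous Diploid Genome Assemblies by Read Depth
    and Pseudo Genetic Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream curation of long-read assemblies of highly
    heterozygous diploid plant genomes. Provides contig purging and
    contamination screening (length cutoff, white/black-list
    classification, low-coverage screen, organelle detection),
    reference-guided contig ordering and orientation via a pseudo
    genetic map built from 1-kb chunks of a related species'
    pseudochromosomes, read-depth classification of gene models into
    phase-separated and merged haplophase classes, heterozygous-variant
    summaries per gene, gene-model filtering by database score ratios,
    reciprocal-best-hit allele pairing with a score-margin rule, and a
    haploid gene-number estimate. A synthetic diploid genome simulator
    with block-structured heterozygosity generates assemblies, depth
    tracks, variant calls and alignment hit tables with known truth so
    that every stage is testable without external data or aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    rtracklayer,
    GenomicRanges,
    IRanges,
    vcfR,
    S4Vectors,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
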