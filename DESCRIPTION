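Package: GenomeRings
Title: Circular BLAST Ring Images for Prokaryote Genome Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds multi-ring circular comparison images for prokaryote
    genomes. One or more reference sequences (FASTA, GenBank or EMBL) form a
    concatenated central coordinate system; query genomes, gene panels or
    unassembled reads are compared against it with BLAST (blastn, blastx,
    tblastx) and each query's hits are drawn as an annulus whose opacity
    encodes percent identity between user thresholds. Additional rings show
    GC content and GC skew in sliding windows, per-base read coverage from
    SAM or ACE assembly files, contig boundaries of draft assemblies, custom
    numeric graphs and feature annotations. A deterministic SVG/SVGZ renderer
    produces the final image; JSON profiles persist complete sessions, and a
    synthetic-data generator (genomes, mutated variants with known deletions,
    reads, SAM, BLAST tabular) makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    BiocGenerics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
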