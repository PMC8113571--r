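Package: ssrscape
Title: Genome-Wide Discovery of Polymorphic Microsatellite (SSR) Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Mines perfect simple sequence repeats (SSRs, di- to
    hexanucleotide motifs) from a reference genome, applies locus-level
    filters (primer designability, A/T-only motifs, proximity), genotypes
    repeat-length variation in silico across resequenced accessions from
    read alignments under a geometric stutter error model, screens loci
    for polymorphism across the panel with a stage-by-stage filter ledger,
    and characterises markers with diversity statistics (number of
    alleles, expected heterozygosity, polymorphism information content),
    principal components, Jaccard distances and neighbor-joining trees.
    Includes a deterministic synthetic-data generator (reference with
    planted SSR loci, diploid accession panel, stutter-noised pre-aligned
    reads) so the full pipeline can be exercised and verified against
    known truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    ape,
    stats,
    tools,
    utils
Suggests:
    Rsamtools,
    vcfR,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
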