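Package: aflpscan
Title: In Silico AFLP Digestion and Marker-to-Gene Genome Distribution
Version: 1.0.0
Authors@R: person("aflpscan", "developers", email = "aflpscan@example.org",
    role = c("aut", "cre"))
Description: Simulates complete double digestion of annotated genomes with
    AFLP enzyme pairs, derives restriction fragments and electrophoretic
    bands, and quantifies the genomic distribution of the resulting markers
    relative to gene locations: windowed landscapes of fragments, bands,
    cut sites and GC content; marker-to-gene distance summaries with random
    and Poisson expectations; candidate-gene subset analyses; and a
    cross-species marker-density regression. Includes a synthetic genome
    generator (GC-contrasted genic/intergenic composition, pericentromeric
    tandem repeat arrays, planted cut sites) so the whole pipeline is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    tools,
    data.table,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
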