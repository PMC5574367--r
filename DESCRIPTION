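Package: peaklift
Title: Assembly Migration, QC and Requantification of CAGE TSS Peak Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for migrating CAGE (Cap Analysis of Gene Expression)
    transcription start site peak sets from an old genome assembly to a new
    one. Implements UCSC chain-file interval lifting with a minMatch
    acceptance rule, evidence-based QC classification of lifted peaks into
    fair/problematic/dropped fates, integration of newly called DPI peaks,
    stable versioned peak accessions and coordinate identifiers, nearest-TSS
    transcript/gene re-annotation with class-dependent flanking windows, and
    promoter expression requantification with RLE scale factors and
    tags-per-million normalization. Includes a seeded synthetic-fixture
    generator (paired assemblies, true chains, planted peaks and simulated
    CTSS with truth labels) so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
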