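Package: blockmapr
Title: Genome Assembly Comparison from Alignment Blocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads alignment-block files produced by assembly evaluation
    pipelines (QUAST all_alignments tables, nucmer show-coords output),
    annotates every block with derived features, junction (misassembly)
    end annotations and six related-block counters, and computes block,
    contig and chromosome statistics tables (N50/L50/N90/L90, genome
    fraction, coverage and gaps).  Builds the data behind multiscale
    visualisations: contig-vs-chromosome bubble maps, whole-genome block
    and gap tracks, per-chromosome contig lanes and polarized dotplots.
    A four-command interface (import, calc, plot, report) drives dataset
    import, table calculation, plot rendering and multi-level HTML
    reports.  A seeded scenario simulator emits alignment files with
    known ground truth so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    IRanges,
    S4Vectors,
    jsonlite,
    ggplot2,
    grDevices,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
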