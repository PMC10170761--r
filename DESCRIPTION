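Package: tssmap
Title: Mapping Chromatin-Bound Factor Peaks to Transcription Start Sites of Active Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible analysis toolkit for ChIP-seq peak
    sets of a chromatin-bound factor, built around the question of whether the
    factor is selectively targeted to transcription start sites (TSSs) of
    active genes. Provides genomic-interval algebra and readers/writers for
    BED/narrowPeak, GTF, bedGraph and TSV; replicate concordance and consensus
    peak construction; TSS-proximity classification; genomic-element
    enrichment against a random background; narrow versus broad gene-body
    occupancy classification; RPKM reference-point and scaled gene-body signal
    metaprofiles; expression-quartile stratification of occupancy;
    differential-expression meta-intersection across timepoints; and
    delta-delta-Ct / fold-over-H3 qPCR statistics. A seeded synthetic-data
    generator plants known ground truth (peak offsets at the +1/-1 nucleosome,
    broad regions on short highly expressed genes, a consistent
    differential-expression core) so that every classifier can be scored
    against truth, and a pipeline driver composes the full analysis under a
    single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
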