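Package: endseqr
Title: Quantification of Meiotic DSB Resection and SPO11-Bound Ends from
    END-seq Read Endpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of END-seq libraries mapping meiotic double-strand
    breaks (DSBs) at SPO11 hotspots. Starting from strand-annotated read
    5'-endpoint positions (BED6), the package builds strand-separated
    endpoint profiles around hotspot centers, quantifies minimum, mean and
    maximum DNA end-resection per hotspot and side, decomposes the central
    (protein-bound) peak into SPO11-bound recombination intermediates
    (SPO11-RI) and unresected SPO11 cleavage complexes (SPO11cc), estimates
    absolute break numbers via a single-DSB spike-in control, and computes
    ChIP-seq-style signal-to-noise quality metrics (FRiP, strand
    cross-correlation, NSC/RSC) adapted to END-seq's reversed fragment
    orientation. A mechanistic simulator of the DSB-processing model
    (resected ends, SPO11-RI, SPO11cc, double-cuts, spike-in cells,
    uniform background) with genotype presets and enzymatic-condition
    filters provides ground truth for every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
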