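Package: sigpile
Title: Signal-to-Sequence Alignment and Pileup Visualization for Nanopore Raw Signal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with nanopore raw-current ("squiggle") data at
    single-base resolution: a compact CIGAR-like encoding of signal-to-sequence
    alignments (the ss tag), conversion of basecaller move tables into
    signal-to-read alignments, projection of those alignments onto a reference
    through read alignments, k-mer-to-base shift correction driven by the most
    significant base of a pore model, multi-read signal pileup layout in time
    scale and molecule scale, and rendering of a self-contained interactive
    HTML browser view. A seeded pore-model signal simulator generates
    fully consistent fixtures (reference, reads, signals, move tables and
    ground-truth alignments) for testing and for simulated comparison tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
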