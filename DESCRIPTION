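Package: proppd
Title: Design and Analysis of Proteomic Peptide Phage Display Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for proteomic peptide phage display (ProP-PD): definition of
    the intrinsically disordered search space of a proteome and its tiling into
    a 16-mer display library, reverse translation into sanitized coding
    oligonucleotides, demultiplexing and normalization of binding-enriched NGS
    selection data, peptide-to-proteome mapping with replicate and overlap
    annotation, short linear motif (SLiM) enrichment with position-specific
    scoring matrices and specificity-determinant p-values, a four-metric
    High/Medium/Low confidence classifier calibrated by ROC/Youden analysis,
    benchmarking and enrichment statistics (binomial, hypergeometric,
    resampling), library-coverage saturation extrapolation, and
    fluorescence-polarization binding models. Includes a synthetic-data
    generator that emulates a full selection campaign for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
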