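Package: mirseed
Title: Small RNA-Seq MicroRNA Discovery, Differential Expression and
    Target Analysis with Planted-Truth Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing analysis toolkit for plant
    microRNA studies with a two-condition (control versus osmotic-stress)
    design. Implements the classical discovery cascade: seven-rule read
    cleaning and unique-tag collapsing, exact-match genome mapping,
    annotation of tags against known miRNAs and structural ncRNA classes
    with single-category priority resolution, novel miRNA prediction from
    excised genomic hairpins folded with a thermodynamic engine and filtered
    by miRNA/miRNA* duplex criteria (minimum free energy, MFEI, A+U content,
    base pairing, bulge and asymmetry limits), tags-per-million
    normalization with the Audic-Claverie exact count test for differential
    expression, penalty-based miRNA target complementarity scoring with
    target-site accessibility, and delta-delta-Ct relative quantification
    for qPCR validation. A synthetic-data generator plants ground-truth
    hairpin precursors, decoy ncRNA loci, contaminant reads and known fold
    changes so that every stage is verifiable by truth-table recovery.
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
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
SystemRequirements: ViennaRNA (RNAfold on the PATH) for hairpin folding
    and target-site accessibility; all other functionality works without it.
Config/testthat/edition: 3
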