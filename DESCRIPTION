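Package: trimscan
Title: Discovery and Evolutionary Analysis of Miniature LTR Retrotransposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Structural discovery and characterization of terminal-repeat
    retrotransposons in miniature (TRIMs): de novo detection of paired-LTR
    elements with target-site duplications, PBS and PPT motifs; recovery of
    solo-LTRs and truncated copies by library scanning; insertion-age dating
    from LTR-pair divergence under the Kimura two-parameter model (T = K/2r);
    randomization tests of genomic distribution and insertion-site
    composition profiling; and element/host phylogenetics with Tamura-Nei
    neighbor-joining, bootstrap support, and Fitch parsimony reconstruction
    of presence/absence histories (MPR enumeration, ACCTRAN/DELTRAN).
    Includes a synthetic-genome simulator that plants elements with known
    coordinates, ages and target-site duplications so every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    igraph,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
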