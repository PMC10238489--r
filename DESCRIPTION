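Package: divquant
Title: Quantification of Cortical Myosin Dynamics and Furrow Kinetics in
    Asymmetric Cell Division
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify cytokinesis in asymmetrically dividing cells
    from single-plane fluorescence time-lapse movies: pole-to-pole cortical
    intensity linescans, cortical enrichment indices, curvature-based
    cleavage-furrow detection, contractile-ring constriction kinetics,
    furrow positioning, and daughter-cell (GMC) morphometrics. Includes a
    synthetic phantom generator for dividing neuroblasts with full ground
    truth (constriction schedule, polar myosin enrichment pulse, optional
    furrow-position correction), cohort statistics (exact two-tailed
    Mann-Whitney, Pearson correlation, median and interquartile range), and
    an exon-junction based estimator of splice-isoform usage with codon
    substitution classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
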