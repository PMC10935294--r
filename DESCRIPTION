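Package: acescreen
Title: In Silico Screening and Kinetic Characterization of ACE-Inhibitory Peptides
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A screening pipeline for food-derived angiotensin-I-converting
    enzyme (ACE) inhibitory peptides. Provides rule-based in silico proteolysis
    of protein sequences (trypsin, papain, and a pepsin-trypsin gastrointestinal
    stage), 5-z-scale amino-acid descriptor encoding of peptides, length-stratified
    two-component partial least-squares (NIPALS) QSAR models of log IC50 with
    t,u-score outlier exclusion and leave-one-out validation, candidate screening
    against observed peptide lists with IC50 thresholds, and enzyme-inhibition
    analysis: inhibition rates, log-logistic dose-response IC50 fitting,
    Michaelis-Menten and Lineweaver-Burk kinetics, and inhibition-mode
    classification. A synthetic-data generator with known ground truth supports
    fully reproducible testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    seqinr,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
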