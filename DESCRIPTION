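Package: ccsplus
Title: Detecting Molecular Convergence with an Empirical Control (CCS+)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the CCS+ framework for detecting molecular
    convergence across independently evolved lineages that share a
    habitat. Site-level convergent amino-acid substitutions are called at
    conservative alignment columns under a symmetric focal/control design
    (Step I), then re-filtered on the full phylogeny with a
    simulation-based noise-retention correction (Step II). The package
    also tests genome-level convergence in amino-acid usage (quartile,
    decile and paired chi-square criteria with a resampling null) and
    estimates the 75 one-step amino-acid exchange rates (Ki) from
    pairwise codon alignments, scoring their deviation from an expected
    cross-taxon spectrum. A sequence simulator under empirical
    amino-acid models (LG) supports noise estimation and fully synthetic
    test data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
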