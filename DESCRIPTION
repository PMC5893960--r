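Package: micscreen
Title: Maximal-Information Association Screening with Permutation
    Significance
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens large variable-by-sample matrices (omics feature
    tables, environmental panels) for pairwise associations of arbitrary
    functional form.  The total information coefficient (TIC_e) serves as a
    high-power independence-test statistic against a rank-based permutation
    null shared by all pairs with the same sample count; empirical p-values
    are corrected for multiplicity (Storey q-values or classical
    procedures) and significant associations are ranked by their maximal
    information coefficient (MIC_e) strength at a sample-size-dependent
    grid resolution.  Includes generators for functional-association and
    cluster-structured benchmark datasets with ground truth, enabling
    power and false-discovery-rate evaluation, plus a command-line
    interface over tab-delimited matrices.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
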