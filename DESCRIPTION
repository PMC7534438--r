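Package: admixtract
Title: Ancestry Tract Lengths Under Adaptive Introgression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic approximation for the length distribution of
    introgressed ancestry tracts around a positively selected allele.
    Models the three-locus ancestral process backward in time as a
    six-state time-inhomogeneous Markov chain driven by the selected
    allele frequency trajectory (closed-form logistic, constant/neutral,
    or a conditioned mean trajectory estimated by Wright-Fisher
    simulation), converts its solution into the along-genome ancestry
    switch rate, and integrates that hazard into the tract-length
    distribution, its mean and its standard deviation. Includes a minimal
    forward-in-time diploid admixture simulator with ancestry-junction
    tracking for validation, the neutral sequentially-Markov closed form
    for comparison, and an introgression-dating workflow that accounts
    for selection on the introgressed allele.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
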