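Package: karyograph
Title: Probabilistic Models of Karyotype Evolution on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models karyotype evolution as a continuous-time Markov walk on
    the karyograph, the lattice of haploid arm number (x) and haploid
    chromosome number (y) with y <= x <= 2y. Centric fusion and fission
    move a karyotype vertically, intra-chromosomal centromere movement
    (A-M and M-A transitions) moves it horizontally, and optional
    whole-genome doubling jumps (x, y) to (2x, 2y). Provides the analytic
    stationary distribution of the walk and its moments, forward
    simulation of karyotypes along trees, maximum-likelihood inference
    under Mk-n and multi-state speciation-extinction (MuSSE-type)
    likelihoods with the M0-M4 model ladder, likelihood-ratio tests,
    marginal ancestral-state reconstruction with credible-range
    summaries, polyploidization-event detection, and branch-length
    fitting with Expected/Conservative/Rapid/Unusual classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
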