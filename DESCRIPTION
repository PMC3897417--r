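Package: partialFIS
Title: Exact Distributions of the Inbreeding Coefficient under Partial
    Asexuality in Finite Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact population-genetics Markov chain for a biallelic diploid
    locus in a finite population reproducing by a mixture of clonal
    (asexual) and sexual events, with reciprocal mutation. Enumerates all
    genotypic states, builds the exact multinomial transition matrix,
    solves for the stationary distribution, and summarises it as discrete
    distributions of the inbreeding coefficient F_IS and of within- and
    between-individual allelic identities, sign and fixation
    probabilities, four distribution moments, state probability rankings,
    and one-generation sign-transition fluxes. Includes the deterministic
    infinite-population recursion and an independent forward Monte-Carlo
    simulator used as a cross-check.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
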