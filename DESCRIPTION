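Package: silocus
Title: S-Locus Genetics of Sporophytic Self-Incompatibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the genetic dissection of sporophytic
    self-incompatibility (SSI) from sequence-typing and controlled-cross
    data. Phases S-haplotypes from presence/absence typing of S-locus
    receptor kinase (SRK)-like sequence labels combined with
    co-segregation in offspring cohorts; tests Mendelian segregation of
    S-locus genotypes with a Monte-Carlo multinomial procedure; infers
    per-organ (pollen/stigma) expression and dominance relations among
    S-haplotypes from diallel cross outcomes and predicts cross
    compatibility under the sporophytic rule; estimates codon-aware
    synonymous and nonsynonymous nucleotide diversity (pi_S, pi_N) by
    unweighted pathway counting; and simulates complete SSI datasets
    (haplotypes with linked sequence labels, diploid panels, cohorts,
    noisy cross outcomes) so that every stage of the pipeline can be
    validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
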