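Package: nectarpe
Title: Priority Effects and Alternative States in Nectar Microbial Communities
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for studying priority effects between
    nectar-colonizing bacteria and yeasts: multinomial (CLAM-style)
    classification of flowers into dominance states with an independence
    null for co-dominance, dip-statistic and Gaussian-mixture analysis of
    nectar pH multimodality, priority-effect strength metrics from
    microcosm growth experiments, and downstream evolve-and-resequence
    genomics (loss-of-heterozygosity calling, permutation divergence
    tests, Weir-Cockerham FST, singleton de novo mutation calling with
    mappability filtering and nearest-gene annotation). Includes seeded
    synthetic-data generators that emulate the statistical structure of
    each input, with truth logs for recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    mclust,
    quadprog,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
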