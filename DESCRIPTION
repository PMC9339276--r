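Package: ctxsub
Title: Context-Dependent Nucleotide Substitution Analysis for Noncoding DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates context-dependent nucleotide substitution matrices from
    aligned ingroup/ingroup/outgroup sequence triplets of noncoding DNA, with
    the flanking hexanucleotide (or narrower/wider) context treated explicitly.
    Provides reverse-complement canonicalization of contexts, per-context
    transition matrices and substitution rates with Wald intervals, stationary
    (equilibrium) base compositions and skews, flanking-composition indices
    (ATI, RI, RATI), CpG contingency analysis with odds ratios and chi-square
    heterogeneity tests, nearest-neighbor duplex stability scores, outer
    neighbor-pair conditioning, a strand-symmetry orientation procedure, and an
    exact (Gillespie-type) simulator of neighbor-dependent sequence evolution
    on three-taxon trees for validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
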