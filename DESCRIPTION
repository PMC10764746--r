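Package: qtlPyramid
Title: Pyramiding Analysis of QTL Epistasis in Substitution-Line Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of multi-environment randomized-block trials of
    single-segment substitution lines (SSSLs) and their pyramids.  Fits the
    mixed linear model y = mu + E + G + GE + B + e with MINQUE(1) variance
    components and BLUP prediction of genotypic and genotype-by-environment
    effects, then hierarchically decomposes genotypic values into additive,
    dominance, pyramiding, dual-, triple- and mixed-epistatic components with
    per-environment interactions and significance tests.  Includes a
    synthetic-data generator with exported ground truth, sign-pattern
    (homeostasis) summaries, and inference of promote/inhibit relationships
    between loci from background-dependent effect changes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
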