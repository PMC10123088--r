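Package: bisreact
Title: Non-Denaturing Bisulfite Reactivity as a Probe of DNA Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for non-denaturing bisulfite probing of
    double-stranded DNA. Converts per-base pileup counts into strand-folded
    per-cytosine conversion (reactivity) estimates, quantifies the polar
    3'-to-5' reactivity gradient across poly-dC:dG mononucleotide runs,
    measures flanking-base and A-tract effects with a quasibinomial model,
    relates poly-C run ends to nucleosome dyad position and roll bending,
    regresses reactivity and motif content against loop-seq cyclizability
    of 50-mers, and computes CpG-excluded per-motif de novo mutation rates.
    Includes a synthetic-data generator that plants recoverable gradients,
    flanking effects, dyad enrichment and mutation rates for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
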