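Package: codiverge
Title: Host-Symbiont Codivergence from Coding-Sequence Alignments and Read Depth
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding how an endosymbiont such as Wolbachia was
    acquired by its insect hosts. Reads per-gene coding alignments, applies a
    single-copy/full-length ortholog filter, concatenates and indexes sites by
    codon position; estimates pairwise divergence with Jeffreys binomial
    intervals and fits a strict-clock chronogram with per-codon-position rate
    multipliers by maximum likelihood with parametric-bootstrap intervals;
    computes Nei-Gojobori (1986) synonymous and nonsynonymous substitution
    rates; classifies the mode of symbiont acquisition (cladogenic,
    introgression, horizontal) against published cladogenic calibration
    ratios and converts divergences to calendar time under explicit rate
    conventions; and calls copy-number variants from normalized read-depth
    profiles with Kolmogorov-Smirnov significance. A synthetic-data module
    generates every input the pipeline consumes, with truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
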