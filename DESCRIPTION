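Package: paleonif
Title: Metal-Dependence Inference for Extant and Ancestral Nitrogenases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers the active-site metal dependence (Mo, V, or Fe) of extant,
    uncharacterized, and ancestral nitrogenase sequences from active-site
    sequence features. Provides JTT substitution-model machinery and
    three-component amino-acid site distributions; structure-based extraction
    of cofactor-contacting residues with reference-frame position mapping;
    marginal ancestral sequence reconstruction on fixed rooted trees with
    Bayesian ancestor sampling and parsimony gap inference; a weighted
    one-versus-rest radial-basis support-vector classifier of cofactor
    specificity with hyperplane-distance support; grid-based binding-pocket
    volume calculation with van der Waals carving, convex-hull and contiguity
    filters; percent-identity and clade-unique-residue comparisons; and a
    seeded synthetic nitrogenase-family generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    e1071,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    Matrix,
    quadprog,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
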