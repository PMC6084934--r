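Package: codonEvolve
Title: Evolutionary Optimization and Optimality Measures for Genetic Codes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Explores the space of hypothetical genetic codes that keep the
    three canonical stop codons fixed. Provides four structural models of
    code variation (degeneracy-preserving, block-preserving,
    codon-number-preserving and unrestricted), an archive-based elitist
    evolutionary algorithm that minimizes or maximizes the polar-requirement
    cost of single-nucleotide changes per codon position, exact big-integer
    code-space counts, and optimality and structure measures (global
    distance, Euclidean distances to extreme-code sets, normalized Hamming
    structure distance) for placing the standard genetic code among the
    best and worst achievable codes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
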