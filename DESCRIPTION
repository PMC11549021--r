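Package: kmersketch
Title: Context-Free k-mer Selection Schemes Under Reverse-Complement Folding
Version: 0.1.0
Authors@R:
    person("kmersketch", "developers", email = "kmersketch@example.org",
           role = c("aut", "cre"))
Description: Tools to construct and audit context-free k-mer sketching
    schemes (syncmers, parameterized syncmers, fractional/hash sets,
    Mykkeltveit-type minimum decycling sets) when k-mers are folded with
    their reverse complements into canonical space. Quantifies window
    guarantees through strongly connected components and longest remaining
    paths of the de Bruijn graph, detects sketching deserts in sequences,
    canonicalizes and symmetrizes selection sets, sparsifies them greedily,
    and designs minimum symmetric decycling sets exactly via a maximum
    nilpotent submatrix formulation solved by branch and bound.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
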