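Package: ringhop
Title: Exit-Vector Aligned Bioisostere Search for Aromatic Heterocycles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds filtered virtual libraries of optionally functionalized
    mono- and bicyclic aromatic heterocycles, aligns library members to a
    query heterocycle through user-specified exit-vectors (aromatic C-H or
    N-H bonds treated as attachment points), and ranks them by a combined
    Gaussian-volume shape Tanimoto and Gaussian-kernel electrostatic
    potential similarity. Includes one-vector and geometry-hashed two-vector
    search modes, iterative partial equalization of orbital electronegativity
    (Gasteiger) charges, fragment-level physicochemical descriptors,
    retrospective shape/ESP weight optimization against bioactivity data,
    and enrichment-factor evaluation of ranked output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
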