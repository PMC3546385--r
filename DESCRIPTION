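Package: rutsim
Title: Constrained Random-Mating Pedigree Simulations for Polygynous
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for testing nonrandom mating in polygynous pedigrees
    with overlapping generations, modelled on long-term individual-based
    studies of harem-breeding ungulates. Provides pedigree kinship,
    relatedness and inbreeding computations; rut-census handling with
    oestrus-window backdating; six constrained random-mating null schemes
    (fully random, temporally constrained, spatially constrained at two
    radii, and age- or breeding-success-weighted sampling) with
    simulation ensembles; re-mating and intralineage-polygyny statistics
    compared to the null by one-tailed Z tests with Bonferroni
    correction; a permutation test for spatial genetic structure of
    rutting males; and a synthetic-study generator with tunable mate
    fidelity, harem monopolisation and male natal-site philopatry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
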