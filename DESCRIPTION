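Package: grassvlad
Title: Grassmannian VLAD Encoding of Histological Images via Higher-Order
    Linear Dynamical Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models each patch of an RGB histological image as a higher-order
    linear dynamical system identified through a Tucker (higher-order SVD)
    decomposition, maps every identified system to a point on the Grassmann
    manifold through its orthonormalized observability matrix, aggregates each
    image's cloud of Grassmannian points into a VLAD code against a codebook of
    Karcher means, and classifies the codes with a radial-basis-function SVM.
    Includes a seeded synthetic texture generator with known class-conditional
    dynamics for parameter-recovery and end-to-end benchmarking, image-level and
    patient-level evaluation protocols, and tidy accessors for every result.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jpeg,
    quadprog,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
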