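Package: monodomainhp
Title: High-Order Hierarchical Finite Elements for the Cardiac Monodomain Equation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves the cardiac monodomain reaction-diffusion equation coupled
    to the Luo-Rudy 1991 ionic model with p-version hierarchical finite
    elements on intervals and unstructured triangular meshes. Cell-state
    variables are carried at Gauss-Lobatto nodal points of configurable degree
    and the ionic current is injected into the weak form by a nodal-to-
    hierarchical change of basis followed by matrix-based right-hand-side
    assembly. Includes built-in mesh generators (1D intervals, unit squares,
    squares with circular holes), rule-based fibre fields (fixed-axis, cubic
    polynomial angle fields and Laplace-Dirichlet fields that wrap around
    holes), a semi-implicit backward Euler time loop with ILU-preconditioned
    conjugate gradients, continuity-repaired ionic rate functions, and
    post-processing for activation times, conduction velocities, error norms
    and convergence orders.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    Matrix,
    methods,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
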