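Package: ciliaflow
Title: Cilia-Driven MHD Micropolar Nanofluid Transport in an Asymmetric Channel
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Solves the lubrication-limit boundary-value problem for
    magnetohydrodynamic micropolar nanofluid transport driven by metachronal
    ciliary beating in a two-dimensional asymmetric channel. The coupled
    stream-function, temperature, nanoparticle-concentration and microrotation
    equations (Buongiorno nanofluid closure with Brownian motion and
    thermophoresis, Joule heating, Darcy drag) are solved by adaptive
    fourth-order collocation, with independent shooting and finite-difference
    solvers for cross-validation. Postprocessing computes skin friction,
    Nusselt and Sherwood numbers at both walls and the axial pressure
    gradient; parameter sweeps report monotonicity trends of centre-line
    quantities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
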