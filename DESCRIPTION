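Package: mucosim
Title: Mucociliary Drug Dissolution and Transport in Airway Surface Liquid
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Three-dimensional simulator of inhaled-drug dissolution,
    transport, ciliary attachment and epithelial absorption in the airway
    surface liquid (ASL). The ASL is modelled as a two-layer film (Newtonian
    periciliary liquid under a five-mode Giesekus viscoelastic mucus layer)
    driven by beating cilia through a direct-forcing immersed boundary
    method on a staggered finite-difference grid with a pressure-projection
    scheme. Dissolved drug obeys a convection-diffusion equation advanced by
    an explicit three-step Runge-Kutta method with iterated immersed-boundary
    mass sources for ciliary attachment; single-particle dissolution follows
    Noyes-Whitney kinetics with a dynamic diffusion-layer thickness. Includes
    analytic verification cases, miniature fixtures, summary metrics
    (deposition fractions and times) and VTK/CSV writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    jsonlite
Config/testthat/edition: 3
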