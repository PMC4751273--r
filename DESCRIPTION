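Package: periclear
Title: Simulation of Perivascular Solute Clearance from Brain Gray Matter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-compartment transport model of solute clearance from brain
    gray matter. Tracer diffuses through the extracellular space with a
    tortuosity-scaled effective diffusion coefficient, is taken up at a
    first-order rate into the basement membranes of cerebral capillaries and
    arteries, and drains convectively along those membranes toward the brain
    surface. The package provides the physical parameter set and dimensionless
    number utilities (Courant, Peclet), a generator for rasterized synthetic
    brain-slice geometries with gray/white matter regions and an injection
    needle, a CFL-stable explicit finite-difference solver for the coupled
    advection-diffusion-uptake equations, detection-distance metrics, and a
    case runner that reproduces the diffusion-only versus drainage simulation
    suite on coronal-like and sagittal-like mouse brain slices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
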