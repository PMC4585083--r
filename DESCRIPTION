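Package: ventriflow
Title: Image-Based Left-Ventricular Hemodynamics with a Moving-Boundary
    Immersed Boundary Solver
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of intraventricular blood flow driven by
    a prescribed, conformal, time-varying endocardial surface.  Provides a
    synthetic moving-ventricle generator (prolate-spheroid lumen with atrial
    and aortic tube extensions, volume waveforms built from end-diastolic and
    end-systolic volumes), a greedy kernel-based diffeomorphic surface
    registration stage producing conformal surface sequences, a sharp-interface
    immersed-boundary incompressible Navier-Stokes solver on a Cartesian grid
    (second-order projection method, Adams-Bashforth/Crank-Nicolson time
    stepping, geometric multigrid pressure solver, multi-dimensional ghost-cell
    wall treatment), Lagrangian particle tracking with the four-component
    ventricular transport decomposition (direct ratio, washout ratio, residual
    ratio, washout cycle count), vortex and pressure-volume-loop diagnostics,
    and a closed-loop Windkessel circulation with time-varying-elastance
    chambers for pre- and after-load.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
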