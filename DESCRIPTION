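Package: pulsewss
Title: Pulsatile Velocity Profiles and Wall Shear Stress from 1D Velocity
    Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs time-varying radial velocity profiles, volumetric
    flow rate, wall shear stress (WSS) and the oscillatory shear index (OSI)
    in conduit arteries from a time-averaged vessel diameter and a
    one-dimensional velocity waveform, using the velocity-driven Womersley
    solution for laminar pulsatile pipe flow alongside the quasi-steady
    Poiseuille approximation used in clinical practice.  Includes a synthetic
    physiologic waveform generator, a finite-difference solver of the
    unsteady axisymmetric momentum equation for independent verification,
    and summary metrics contrasting the two reconstruction methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
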