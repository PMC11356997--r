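Package: porewalk
Title: Brownian Dynamics of Spherocylindrical Particles in a Cylindrical Channel
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Overdamped Wiener-process simulator of rigid spherocylindrical
    (capsule-shaped) particles diffusing through a cylindrical channel with a
    reflecting entrance and an absorbing exit, together with the analyses used
    to characterise confined transport: mean squared displacement with
    diffusion-constant and diffusion-type exponent fitting, first-passage-time
    survival statistics with exponential tail rates, and exit-orientation
    distributions with sphere-measure reweighting. Rotational step sizes follow
    energy equipartition through the particle's inertia tensor. Includes
    ensemble execution with reproducible per-trajectory seeding, parameter
    sweeps over particle aspect ratio and diameter, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    survival,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
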