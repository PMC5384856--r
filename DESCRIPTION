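Package: shellfield
Title: Hydration-Shell Electric Fields at the DNA Backbone Phosphate and
    Ultrafast Pump-Probe Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling the coupling between a phosphate probe and
    its water shell. Generates equilibrium hydration-shell configurations
    around a rigid dimethylphosphate solute by rigid-body Metropolis Monte
    Carlo with a five-site water model, evaluates the solvent electric field
    at the PO2- group (point charges, dipoles and traceless quadrupoles)
    projected on the C2 symmetry axis, and analyses radial distribution
    functions and temperature-resolved field distributions. A vibrational
    Stark mapping converts field changes to band shifts and difference
    spectra. Pump-probe transient-absorption kinetics are simulated and
    fitted with mono-exponential and biphasic models, including global fits
    with shared time constants, and an excitation-dosimetry calculator gives
    the excited-molecule fraction and hot-ground-state temperature jump.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
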