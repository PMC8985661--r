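Package: motormap
Title: Stochastic Lattice Simulation of Kinesin Regulation by
    Microtubule-Associated Protein 7
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Kinetic Monte Carlo simulation of kinesin-1 and dynein motility
    on microtubule lattices decorated with MAP7, under a mutually exclusive
    site-occupancy rule. Implements MAP binding equilibria and Gillespie
    decoration kinetics, event-driven motor runs with projection-domain
    tethered diffusion and obstacle encounters, changepoint step detection
    for noisy single-molecule trajectories, direction classification, and
    Hill / biphasic Hill / Langmuir dose-response fitting, together with
    synthetic-data generators for titrations, trajectories and kymographs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
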