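Package: sonochamber
Title: Acoustic Design of Microliter-Scale Ultrasound Exposure Chambers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing and characterizing thin, rigid-walled
    microliter-scale chambers used to expose cells, vesicles and
    microbubbles to ultrasound under a microscope. Provides a material
    property registry with acoustic impedances and power-law attenuation,
    single-interface plane-wave transmission at normal and oblique
    incidence with critical and intromission angles, transfer-matrix and
    global-matrix solvers for layered fluid/solid stacks (including
    shear-wave conversion and thin-gap standing-wave interference),
    semi-analytic flat and focused piston transducer fields with focal
    metrics, lipid-shelled microbubble resonance and mechanical index,
    and an end-to-end chamber evaluation pipeline with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    pracma,
    purrr,
    readr,
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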