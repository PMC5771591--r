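Package: cardiomef
Title: Mechano-Electric Feedback in a Contracting Ventricle Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multiscale simulator of the contracting cardiac ventricle with
    mechano-electric feedback. A human mid-myocardial ventricular myocyte
    ionic model (ten Tusscher-Noble-Noble-Panfilov 2004 formulation) is
    extended with a stretch-activated channel current, coupled to a
    Negroni-Lascano style myofilament model and a fiber-ring ventricle with
    isotropic monodomain propagation and lumped haemodynamics. Provides
    single-cell and tissue protocols for studying preload-dependent changes
    in activation, recovery, and action potential duration under normal and
    heart-failure conditions, plus activation/recovery marker extraction and
    pressure-volume loop analysis.
License: MIT + file LICENSE
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
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    readr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
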