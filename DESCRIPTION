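Package: tg43film
Title: Radiochromic Film Dosimetry of HDR Ir-192 Brachytherapy Sources in the TG-43 Formalism
Version: 0.1.0
Authors@R:
    person("NSTRI", "Dosimetry Tools", email = "dosimetry@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing high-dose-rate (HDR) Ir-192
    brachytherapy sources with radiochromic film in the AAPM TG-43
    formalism. Implements the line-source geometry function and dose-rate
    equation, a seeded virtual experiment that renders film scans from a
    ground-truth source model (calibration strips, background films,
    film-uniformity and scanner noise), a scan-to-dose analysis chain
    (optical density, polynomial calibration, polar dose-rate maps),
    extraction of the dose rate constant, radial dose function and 2D
    anisotropy function, and Type A/B quadrature uncertainty budgets with
    inter-method comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
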