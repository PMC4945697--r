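Package: aorta0d
Title: Reduced-Order Haemodynamic Modelling of Aortic Dissection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lumped-parameter (0D) simulation of blood flow in the dissected
    aorta. Provides a time-varying elastance model of the left heart with
    diode valves, three-element Windkessel outlet models, a configurable
    true-lumen/false-lumen network with connecting intimal tears solved by
    implicit time stepping to cyclic convergence, pressure-volume loop and
    stroke-work quantification, an elastance tuning loop that matches a
    target cardiac output, measurement-versus-simulation comparison
    statistics, and a synthetic generator for PC-MRI-like inflow waveforms
    and per-lumen flow measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
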