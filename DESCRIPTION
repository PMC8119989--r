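Package: proxsir
Title: Distance-Coupled SIR Epidemic Models with Prevalence-Driven
    Social Distancing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates an SIR epidemic model in which the transmission
    rate is a decreasing convex function of the average interpersonal
    distance that individuals keep, and that distance is itself a
    dynamic variable: it grows in proportion to observed point
    prevalence and relaxes back towards a culturally determined
    natural-distance.  Provides four transmission-rate functional
    forms, basic reproduction numbers, closed-form and integral
    identity validators for the distance law and susceptible
    depletion, final-size computations, epidemic peak detection with
    prominence filtering, scenario presets for three society types
    (small, medium and large natural-distance), parameter sweeps, a
    YAML scenario configuration format and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
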