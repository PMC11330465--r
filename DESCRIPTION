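Package: rebreathe
Title: Breath-by-Breath Detection of CO2 Rebreathing During Bilevel
    Ventilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing carbon dioxide movement in single-limb
    bilevel positive airway pressure (BiPAP) leak circuits. Includes a
    physical simulator of gas transport through the leak port with
    per-cycle ground truth, waveform input/output with a CSV + JSON
    sidecar convention, sidestream-capnometer delay compensation, breath
    segmentation by flow zero-crossings, extraction of 17 per-cycle
    respiratory parameters, rule-based cycle typing (I/II/III) from
    ventilator-side CO2, a statistical battery (one-way ANOVA,
    Newman-Keuls pairwise comparisons, canonical discriminant analysis),
    and a CO2-free multilayer-perceptron classifier evaluated by tenfold
    cross-validation with pooled ROC curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
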