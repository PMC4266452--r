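Package: qtsim
Title: Action Potential Simulation of Multi-Channel Drug Block for QT
    Safety Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-silico cardiac safety pipeline. Fits Hill
    concentration-effect curves to ion channel screening data (pIC50s for
    hERG, CaV1.2, NaV1.5, KCNQ1 and Kv4.3), applies conductance-block
    scaling to three human ventricular action potential models (ten
    Tusscher-Panfilov 2006 epicardial, Grandi-Pasqualini-Bers 2010
    epicardial, and O'Hara-Rudy 2011 endocardial), paces each model at
    1 Hz to pseudo-steady state with an adaptive stiff solver, and builds
    concentration versus change-in-APD90 curves over a 20-point
    logarithmic concentration grid.  Assay variability is propagated into
    95 percent credible bands by resampling pIC50s, and predictions are
    scored against Thorough QT study outcomes with fold-change
    concentration windows, yielding contingency tables with sensitivity,
    specificity and accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
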