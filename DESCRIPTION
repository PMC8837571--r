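Package: vpaxis
Title: Virtual-Patient Analysis of the HPA Stress Axis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a sigmoidal-network ordinary-differential-equation
    model of the hypothalamic-pituitary-adrenal (HPA) axis under a transient
    stress protocol, generates heterogeneous virtual-patient cohorts by
    uniform parameter sampling, classifies each patient by post- versus
    pre-stress steady-state cortisol (higher, lower or control), ranks the
    discriminating parameters with random-forest permutation importance,
    decision trees and support-vector machines, and explains the classes
    mechanistically with numerical bifurcation analysis (pseudo-arclength
    continuation of equilibria, saddle-node and Hopf detection, two-parameter
    fold following).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    randomForest,
    rpart,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
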