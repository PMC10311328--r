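Package: wildmoments
Title: Moment Estimation for Chemical Master Equations with Fat-Tailed Solutions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying how statistical moment estimation behaves when
    the solution of a chemical master equation is fat-tailed and the moments
    being estimated do not exist. Provides a direct-method Gillespie stochastic
    simulation engine for one-species reaction networks, a truncation-closure
    method-of-moments engine with finite-time blow-up detection, exact reference
    distributions (including a discrete inverse-square law that is the
    stationary solution of a quadratic birth-death network), prefix-sample
    moment estimators with dominance diagnostics, and fat-tail detectors based
    on log-log tail slopes and SSA step-count distributions.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
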