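Package: huvsd
Title: Hierarchical Unequal-Variance Signal Detection for Binary Responses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits hierarchical Gaussian signal detection models to binary
    yes/no response data (per-participant hits, false alarms and trial
    totals).  The unequal-variance model (hUVSD) estimates the signal
    distribution's standard deviation at the population level from the
    between-participant variability of z-transformed hit and false-alarm
    rates, alongside population means and variances of sensitivity and
    criterion.  Includes the equal-variance baseline (hEVSD, plain and
    linearly expanded), a closed-form moment estimator derived from the
    bivariate-normal structure of the z-transformed rates, a self-contained
    Metropolis-within-Gibbs sampler with split-Rhat diagnostics and DIC/WAIC
    model comparison, a synthetic-data generator with assumption-violation
    modes, and runners for parameter-recovery, misspecification-bias and
    robustness simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, coda
Suggests: testthat (>= 3.0.0), rjags, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
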