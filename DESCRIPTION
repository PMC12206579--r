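Package: lvfill
Title: Non-Invasive Estimation of Left-Ventricular Diastolic Pressures
Version: 0.1.0
Authors@R: person("lvfill", "maintainers", email = "lvfill@example.org",
    role = c("aut", "cre"))
Description: Estimates left-ventricular (LV) diastolic pressures (minimum
    P_LV, pre-atrial-contraction P_LV, end-diastolic P_LV) and the
    isovolumic relaxation time constant tau from echocardiography-derived
    inputs: a global longitudinal strain trace, a mitral inflow velocity
    trace, and scalar measurements (cuff systolic pressure, BMI, left
    atrial reservoir strain, LV volumes). Combines a Weiss exponential
    relaxation model, a simplified Navier-Stokes transmitral pressure
    gradient, and a multivariable regression for minimum P_LV in a coupled
    fixed-point solver, and reconstructs a patient-specific diastolic
    pressure curve from a time-normalized reference template. Includes a
    forward simulator of synthetic patients for end-to-end validation and
    Bland-Altman agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
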