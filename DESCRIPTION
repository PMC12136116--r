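Package: mfvep
Title: Multifocal Visual Evoked Potential Analysis with Retinotopically
    Constrained Source Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing multifocal visual
    evoked potential (mVEP) experiments. Provides maximal-length binary
    sequence generation with pulse thinning and time-lagged multi-location
    pulse trains; EEG conditioning (windowed-sinc low-pass filtering,
    spherical-spline channel interpolation, average referencing, piecewise
    linear detrending); deconvolution of per-location evoked waveforms by
    lagged regression; global-field-power and topographic component
    analytics; a three-shell concentric-spheres dipole forward model with
    parametric retinotopic source placement; retinotopically constrained
    source regression with sliding-window fits, forward-selection BIC and
    participant bootstrap; and a forward-model EEG simulator with retained
    ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
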