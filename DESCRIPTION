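Package: neurocat
Title: Quantitative Neuromotor Test Battery: Tremor, Motor Speed, and
    Postural Sway
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hardware-free implementation of a portable computerized
    neuromotor test battery of the kind used in movement-disorder and
    occupational-neurotoxicology research. Computes spectral tremor metrics
    (band-limited tremor intensity, median power frequency, frequency
    dispersion, harmonic index) from accelerometer traces, tapping and
    simple-reaction-time metrics with anticipatory-response filtering,
    and static-posturography sway metrics (transversal/sagittal/mean sway,
    convex-hull sway area, sway velocity and intensity) from three-point
    force-plate recordings. Includes the standardized evaluation protocol,
    seeded synthetic-signal and cohort generators emulating parkinsonian
    and control performance, and the nonparametric group-comparison and
    clinical-correlation statistics used with such batteries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
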