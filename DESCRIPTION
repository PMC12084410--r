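Package: sansshape
Title: Shape-Model Fitting for Small-Angle Scattering of Ring Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Form-factor modelling and global fitting of reduced 1-D
    small-angle neutron/X-ray scattering curves, built around a dumbbell
    model for hexameric ring proteins (two coaxial ellipsoids of
    revolution pierced by an axial cylindrical channel) and the polymer
    excluded-volume model for flexible proteins. Provides exact numeric
    and closed-form scattering amplitudes with orientational averaging,
    particle-swarm curve fitting with resolution smearing, Guinier and
    Porod analysis, Monte-Carlo and Debye-sum oracles for validation, a
    seeded synthetic-data generator, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
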