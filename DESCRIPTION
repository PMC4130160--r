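Package: cryopolish
Title: Particle Polishing for Beam-Induced Motion Correction in Cryo-EM
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates straight per-particle beam-induced movement tracks in
    cryo-EM movies by neighbour-weighted least squares over noisy per-frame
    translations, derives per-frame relative B-factors and intercepts from
    half-set Fourier shell correlation curves via relative Guinier analysis,
    and produces shift-corrected, frequency-weighted ("polished") average
    particles. Includes MRC/MRCS and STAR input/output and a synthetic-data
    generator emulating spatially smooth motion fields and dose-dependent
    signal decay for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
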