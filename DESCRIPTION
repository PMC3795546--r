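Package: luvsaxs
Title: Shell-Model Analysis of Small-Angle X-Ray Scattering from Protein-Encapsulating Liposomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward modeling and analysis of solution small-angle X-ray
    scattering (SAXS) from large unilamellar vesicles (LUVs). Implements the
    orientationally averaged form factor of multi-shell ellipsoidal and
    spherical vesicles integrated over a truncated-Gaussian size
    distribution, the pair-distance distribution function p(r) by direct
    Fourier transform, Guinier analysis of the radius of gyration, bounded
    least-squares fitting of shell-profile parameters scored by the
    reliability factor R, and estimation of the protein encapsulation
    efficiency of a liposome water pool from the decrement of the radius of
    gyration upon protein occlusion. A synthetic-data module generates
    calibrated vesicle fixtures and noisy curves so that the whole pipeline
    runs without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
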