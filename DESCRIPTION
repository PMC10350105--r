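Package: sfxspread
Title: Spatially Resolved Anomalous Dispersion from Simulated Serial
    Femtosecond Crystallography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale toolkit for spatially resolved anomalous
    dispersion (SPREAD) in serial femtosecond crystallography. Provides
    atomic scattering physics (Cromer-Mann form factors, tabulated
    anomalous scattering curves coupled by a finite-grid Kramers-Kronig
    transform, wavelength-dependent complex structure factors), a
    nanoBragg-style forward simulator of diffraction-spot shoeboxes with
    polychromatic spectra, mosaic domains and Poisson noise, a classical
    maximum-likelihood inversion for the K-edge shift of an anomalous
    scatterer with profile-likelihood and bootstrap uncertainty, and a
    physics-informed variational autoencoder that corrects a mis-specified
    forward model and returns a posterior distribution over the recovered
    edge shift.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
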