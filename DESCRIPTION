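Package: quenchbind
Title: Fluorescence Quenching and Thermodynamic Analysis of
    Ligand-Serum Albumin Binding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Spectroscopic binding analysis for small-molecule/serum-albumin
    interactions. Implements Stern-Volmer quenching analysis with
    mechanism classification from the temperature trend, double-logarithm
    (Hill) estimation of association constants and binding-site numbers,
    van't Hoff thermodynamics with interaction-force classification from
    the signs of the enthalpy and entropy changes, site-marker competitive
    displacement analysis, and structural spectroscopy (synchronous
    fluorescence, excitation-emission matrices with Rayleigh-ridge
    handling, UV/Vis peak-shift analysis, and circular dichroism mean
    residue ellipticity with alpha-helix quantification). A seeded
    synthetic-data generator emulates complete titration studies with
    known ground truth so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
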