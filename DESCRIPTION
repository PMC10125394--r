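Package: fixir
Title: Label-Free Assessment of Formalin Fixation from Mid-Infrared Spectra
Version: 0.1.0
Authors@R:
    person("fixir", "maintainers", email = "fixir@example.org", role = c("aut", "cre"))
Description: Tools to estimate the formalin-fixation time of tissue specimens
    from their mid-infrared (MID-IR) absorbance spectra. Includes a synthetic
    study generator (Gaussian amide bands with saturating fixation kinetics,
    scattering baselines, atmospheric contamination, whole-organ spatial
    fixation gradients, and immunohistochemistry fixtures), the standard FTIR
    preprocessing chain (absorbance computation, atmospheric compensation,
    concave rubber-band baseline correction, amplitude normalization, spatial
    averaging), Amide-band deformation metrics via Savitzky-Golay
    differentiation, a NIPALS partial least-squares regression model of
    fixation time with stratified holdout and twofold cross-validated
    component selection, whole-organ fixation mapping, and brightfield IHC
    percent-positivity quantitation with an exact rank-sum test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
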