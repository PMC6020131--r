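Package: deplstab
Title: Depletion Flocculation and Viscosity Stability of Polysaccharide-Emulsion Mixtures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts the colloidal stability of oil-in-water emulsions mixed with
    non-adsorbing polysaccharides (guar gum galactomannan, oat beta-glucans) from two
    coupled hard-sphere models: a relative-viscosity divergence model giving a critical
    viscosity concentration (CVC), and an osmotic depletion-attraction model giving a
    critical flocculation concentration (CFC). The two critical concentrations drive a
    four-regime stability classifier (stable dilute, flocculated and creaming,
    flocculated without creaming, kinetically arrested), tabular phase diagrams, and
    comparison reports against qualitative flocculation observations. Includes seeded
    synthetic generators for polymer families obeying an Rh-Mw power law, lognormal
    droplet populations calibrated to a target Sauter diameter, and oat-extract
    solution fixtures, so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
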