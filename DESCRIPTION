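Package: rumiflux
Title: Enteric Methane Quantification by the SF6 Tracer Technique with
    Rumen Fermentation, Protozoa and Archaeome Summaries
Version: 0.1.0
Authors@R:
    person("Rumiflux", "Developers", email = "rumiflux@example.org",
           role = c("aut", "cre"))
Description: Computational chain for sheep feeding trials that quantify
    enteric methane emission with the sulfur hexafluoride (SF6) tracer
    technique. Covers permeation-tube release-rate calibration, canister
    pressure accounting and concentration correction, daily emission and
    methane yield, volatile fatty acid (VFA) concentrations and the
    stoichiometric metabolic-hydrogen balance, hemocytometer-style rumen
    protozoa enumeration, feeding-trial intake, digestibility and
    performance arithmetic with oil-dose economics, and archaeal amplicon
    sequence variant (ASV) table summaries (pruning, rarefaction, rank
    aggregation, Shannon diversity, core-archaeome filtering, PERMANOVA).
    A seeded forward simulator generates complete synthetic trials with
    the statistical structure the analysis assumes, so the whole pipeline
    is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan,
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
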