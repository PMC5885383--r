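Package: opsfuel
Title: Energy Requirements of Special Operations Training from Doubly
    Labeled Water
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes total daily energy expenditure from doubly labeled
    water (DLW) isotope kinetics: total body water by isotope dilution,
    elimination rates by log-linear regression, CO2 production by the
    Schoeller two-pool equation, and energy expenditure via the Weir
    energy equivalent of CO2.  Derives the energy budget of military
    training courses (resting metabolic rate from fat-free mass,
    diet-induced thermogenesis, activity-induced expenditure, physical
    activity level, energy balance), classifies courses into
    quartile-based physical activity factors (PAF), and evaluates or
    refits linear equations predicting daily energy requirements from
    body mass or fat-free mass plus PAF.  Ships the published course
    reference tables from US Special Operations Forces training studies
    and a synthetic cohort and isotope-series generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
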