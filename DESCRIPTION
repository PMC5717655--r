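Package: huddlesim
Title: Developmental Model of Rodent Huddling from Thermal Physiology to Filial Preference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the ontogeny of huddling in rodent litters. Couples
    closed-form developmental curves for brown-adipose-tissue depletion,
    metabolic entropy, growth and thermal preference to a Monte Carlo
    set-partition model of group formation, and adds a Delta-rule
    odour-heat conditioning layer so that learnt olfactory preferences can
    sustain huddling after the thermal drive wanes. Includes a synthetic
    developmental-data generator and staged nonlinear least-squares
    refitting of the model constants for parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
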