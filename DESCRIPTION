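Package: nmrbind
Title: Solution NMR and Calorimetry Analysis of Tandem-Domain RNA Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis chain used to characterise
    how tandem RNA-recognition motifs engage an RNA element in solution:
    chemical-shift-perturbation (CSP) mapping and HSQC titration binding
    fits in fast exchange, rotational correlation times from 15N T1/T2 with
    an empirical molecular-weight prediction, per-domain versus joint SVD
    fitting of residual dipolar couplings as a test of interdomain rigidity,
    and one-site (Wiseman) and sequential two-site isothermal titration
    calorimetry models. A synthetic-data module generates every input class
    (toy structures, peak lists, relaxation tables, RDC tables, isotherms)
    so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    minpack.lm,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
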