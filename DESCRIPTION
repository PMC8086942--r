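Package: fontanmix
Title: Mixing and Hepatic Flow Distribution in Fontan Conduits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the mixing of hepatic-venous (HV) and inferior-vena-cava
    (IVC) blood streams inside a Fontan conduit and the resulting hepatic flow
    distribution (HFD) to the two pulmonary arteries. Provides an analytic,
    divergence-free, time-periodic duct flow generator with a tunable blinking
    transverse stirring mechanism as a controllable stand-in for patient-specific
    CFD output, Lagrangian particle tracing with plane-transection detection, a
    quadrant-based intensity-of-segregation mixing index with cardiac-cycle
    averages and clinical category labels, HFD quantification by three seeding
    strategies (direct hepatic-vein seeding and conventional caudal/cranial
    conduit seeding), and the method-agreement statistics used to compare them
    (paired t, Bland-Altman limits of agreement, intraclass correlation, mean
    absolute difference, repeated-measures ANOVA with Tukey post hoc). External
    time-resolved velocity fields can be ingested from legacy VTK structured
    grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
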