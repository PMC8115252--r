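Package: neonox
Title: Neonatal Noxious-Evoked BOLD Amplitudes, Resting-State Prediction
    and White-Matter Structure-Function Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying inter-individual
    variability in neonatal noxious-evoked BOLD responses. Implements
    subject-level GLM fitting with a double-gamma haemodynamic response
    function, spatial-regression overall response amplitudes, sign-flip
    cluster inference with variance smoothing, template-expression
    statistics, resting-state network amplitude extraction by spatial
    multiple regression summarised with the median absolute deviation,
    imaging confound computation (framewise displacement,
    stimulus-correlated motion, ROI amplitudes), leave-one-out
    cross-validated linear support vector regression with cross-validated
    confound adjustment and full-pipeline permutation inference, and an
    exploratory-confirmatory white-matter structure-function analysis
    (tract-mean diffusion features, max-statistic FWER screening, mean
    diffusivity principal-component pooling, all-subsets tract
    combinations). A seeded synthetic-cohort generator provides phantom
    maps, 4D runs and tabular features with known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
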