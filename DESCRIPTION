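Package: circaphase
Title: Circadian Phase Prediction from Ambulatory Light and Skin Temperature
Version: 0.1.0
Authors@R: person("Pkg", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts circadian phase (salivary melatonin phase or urinary
    6-sulphatoxymelatonin acrophase) from ambulatory blue-light irradiance and
    skin-temperature recordings using a lagged-input multilayer perceptron
    trained with resilient backpropagation. Includes the full preprocessing
    chain for wrist actigraphy and multi-site skin temperature (cleaning,
    detrending, autoregressive gap interpolation, 30-minute binning and
    alignment), reference-waveform construction from melatonin profiles
    (bimodal skewed baseline cosine fits) and urinary aMT6s excretion rates
    (cosinor fits), center-of-gravity phase calculation, leave-one-out
    cross-validated training and evaluation with circular statistics,
    comparator phase estimators (mid-sleep proxy, normal-range and resampling
    guesses), and a synthetic-cohort generator with known ground-truth phase
    for fixed, habitual and rotating shift-work sleep schedules.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
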