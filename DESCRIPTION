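Package: popformat
Title: Neural Population Formatting, Two-Stage Recurrent Network Models, and
    In-Silico Perturbation of Decision Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how neural populations format sensory and
    reward information and what that formatting implies for behavior. Implements
    a reward-scaled continuous direction-estimation task, gain-modulated von
    Mises tuning simulations, a two-stage recurrent network with a sensory
    (MT-like) module trained to report motion and reward-condition inputs
    separably and a decision (dlPFC-like) module trained to predict expected
    reward for every candidate choice, fixed-point analysis of the trained
    dynamics, a subspace-angle statistic quantifying separable versus joint
    population geometry, a synthetic recording-session generator with exact
    ground-truth formatting angles, and in-silico single-unit perturbation
    experiments with regime classification (vector averaging versus
    winner-take-all).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
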