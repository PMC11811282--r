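Package: cortwin
Title: Digital-Twin Simulation of Cortical Signals with a Hierarchical
    Variational Recurrent Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A hierarchical variational Bayesian recurrent neural network
    that learns to generate multichannel cortical signals, tracks latent
    brain state in real time via sliding-window data assimilation and
    supports virtual interventions on its latent units at three levels
    (global state, functional network, local region). Ships the
    surrounding analysis stack: transfer entropy from network-level
    latents to region dynamics, silhouette and k-NN cluster assessment, a
    multitaper-spectrogram discriminator, the signal preprocessing chain
    (common-median re-reference, outlier-bin exclusion, linear
    normalization, crossfade concatenation), and a synthetic two-regime
    signal generator so the full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    cluster,
    class,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
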