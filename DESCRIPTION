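Package: absampler
Title: Autocorrelated Bayesian Sampler Models of Judgment, Choice, Confidence,
    and Response Time
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Simulates a rational process model in which autocorrelated samples
    from a posterior distribution over fine-grained hypotheses are transformed
    into six behavioral measures: probability judgments, point estimates,
    confidence intervals, choices, confidence judgments, and response times.
    Hypothesis samples are generated by Metropolis-coupled MCMC (parallel
    tempering) with cross-trial carryover of the sampler state, tempered by a
    Beta/Dirichlet prior on responses and terminated by fixed-size or
    max-minus-next optional stopping rules.  Includes signal-detection
    metacognition metrics (d-prime and criterion-dependent meta-d-prime),
    power-spectral slope estimation for 1/f classification of trial series,
    and a configurable battery of simulation experiments covering classic
    effects such as slow and fast errors, anchoring and repulsion,
    subadditivity, the conjunction fallacy, partition dependence, and
    interval-production overconfidence.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
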