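Package: phagevo
Title: Evolutionary Epidemiology of Temperate Phage in Chemostats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic models and statistical inference for the coupled
    epidemiological and evolutionary dynamics of two competing strains of a
    temperate bacteriophage (such as phage lambda) spreading in chemostat
    cultures of bacteria. Provides the delayed-lysis compartmental ODE model
    and its instantaneous-lysis nested variant, closed-form theory (basic
    reproduction numbers, selection gradients on the logit scale,
    differentiation of a variant between life stages), a generator of
    synthetic logit-scale time series with Gaussian measurement error, a
    two-step maximum-likelihood estimation procedure (direct estimation of
    prophage reactivation rates followed by multi-start Nelder-Mead
    optimization of the remaining parameters), profile-likelihood
    identifiability diagnostics, AIC model comparison, and Sieve-bootstrap
    confidence intervals based on ARMA models of the residuals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
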