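# phagevo

Evolutionary epidemiology of a temperate bacteriophage in chemostats:
deterministic models, closed-form theory, and statistical inference for
the competition between two phage strains with different lysis–lysogeny
strategies.

## The problem

A temperate phage (the archetype is phage λ in *E. coli*) can transmit
horizontally — lyse the host, release `B` virions — or vertically, as a
dormant prophage copied at each cell division. When a virulent variant
(lower lysogenization probability `phi`, higher prophage reactivation
rate `alpha`) competes with the wildtype in a chemostat, the direction of
selection depends on the epidemiological state: the virulent strain is
favoured while susceptible cells are abundant and counter-selected once
almost every cell is infected. `phagevo` is for researchers who want to
*quantify* that feedback: simulate it, derive the selection gradients,
and estimate the strains' life-history traits from prevalence and
variant-frequency time series.

The core model tracks seven densities — susceptibles `S`, lysogens
`L_w, L_m`, cells committed to lysis `Y_w, Y_m`, free virions
`V_w, V_m` — with logistic host growth, force of infection `a·b·V_k·S`,
lysogenization with probability `phi_k`, reactivation at rate `alpha_k`,
lysis at rate `tau` releasing `B` virions, and dilution `delta`
throughout. Three analytic results drive the inference:

* the basic reproduction number `R0_k` of each strain at susceptible
  density `S0` (epidemic iff `R0 > 1`);
* the selection gradient of the mutant on the logit scale:
  proportional to `-(phi_m - phi_w)` at the onset, exactly
  `-(alpha_m - alpha_w)` at the end of the epidemic;
* the virion–prophage differentiation (odds ratio)
  `Q^VL -> alpha_m / alpha_w` at high prevalence.

Estimation is two-step: the reactivation rates come directly from the
endemic phase (slope of logit `g` plus geometric-mean differentiation);
the remaining parameters come from a multi-start Nelder–Mead Gaussian
MLE on the logit-scale trajectories, with `B` fixed (only `b × B` is
identifiable). Confidence intervals use a Sieve bootstrap: ARMA models
fitted to the per-chemostat residuals simulate new residual series, and
the whole two-step estimation is repeated.

## Worked example

```r
library(phagevo)

p <- default_params()            # the simulation-study parameter set
basic_reproduction_number(p, "wildtype")
#> R0[wildtype] = 3.3023  (S0 = 1e+09)
basic_reproduction_number(p, "mutant")
#> R0[mutant] = 4.0386  (S0 = 1e+09)

# synthetic experiment: 2 treatments x 4 chemostats, hourly 1-60 h,
# measurement SD 0.01 on the logit scale
d <- generate_dataset(p, design_spec(sigma_P = 0.01, sigma_g = 0.01,
                                     sigma_q = 0.01), seed = 1)

est <- estimate_alphas(d)        # step 1: reactivation rates
est
#> Reactivation-rate estimates (step 1)
#>   slope S = -0.01301 /h, differentiation Q = 2.917 (438 points)
#>   alpha_w = 0.006786 /h, alpha_m = 0.01979 /h

fit <- fit_mle(d, fixed = list(K = 1e9, delta = 0.8, B = 80,
                               alpha_w = est$alpha_w,
                               alpha_m = est$alpha_m),
               n_starts = 50, seed = 1)
fit$theta$phi_w; fit$theta$phi_m
#> [1] 0.1752065
#> [1] 0.01647527
```

The two `R0` values say both strains can invade a fully susceptible
culture, the mutant faster — yet the mutant still loses in the long run,
because once prevalence saturates selection is `-(alpha_m - alpha_w) < 0`.
The step-1 estimates land within a few percent of the generating values
(`alpha_w = 7e-3`, `alpha_m = 2e-2`), and the MLE recovers the
lysogenization probabilities (generating values `phi_w = 0.2`,
`phi_m = 0.02`) to within about 15% at this noise level and number of
starts. `sieve_bootstrap(d, fit)` adds percentile CIs, and
`run_pipeline(default_config(), "out/")` chains all stages and writes
tidy CSV/JSON artifacts plus a manifest. A thin command-line wrapper
(`inst/cli/phagevo`) exposes `r0`, `simulate`, `synth`, `fit-alpha` and
`run`.

See the vignette (`vignettes/phage-evolution-inference.Rmd`) for the
model assumptions, the identifiability analysis and every numerical
choice.

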