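---
title: "Models and inference for temperate-phage evolution in chemostats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and inference for temperate-phage evolution in chemostats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagevo)
```

## The biological system and the model

A temperate bacteriophage spreading in a well-mixed chemostat culture can
transmit in two ways: horizontally, by lysing its host and releasing free
virions, and vertically, by integrating into the host chromosome as a
prophage that is copied at every cell division. `phagevo` models the
competition between two strains that differ in how they balance these
routes: a wildtype with a high probability of lysogenization
$\phi_w$ and a low prophage reactivation rate $\alpha_w$, and a virulent
mutant with the opposite strategy ($\phi_m < \phi_w$,
$\alpha_m > \alpha_w$).

The bacterial population is partitioned into susceptible cells $S$,
lysogens $L_k$, and cells committed to lysis $Y_k$ (phages replicating in
the cytoplasm), with free virions $V_k$ in the medium; $k \in \{w, m\}$
indexes the strain. Writing $N = S + L + Y$, each strain obeys

$$
\begin{aligned}
\dot S &= r S (1 - N/K) - a b V S - \delta S,\\
\dot L_k &= r L_k (1 - N/K) + \phi_k\, a b V_k S - \alpha_k L_k - \delta L_k,\\
\dot Y_k &= (1 - \phi_k)\, a b V_k S + \alpha_k L_k - \tau Y_k - \delta Y_k,\\
\dot V_k &= \tau B Y_k - a N V_k - \delta V_k,
\end{aligned}
$$

where $a$ is the adsorption rate, $b$ the probability that an adsorbed
virion injects its genome, $\tau$ the lysis rate (so $1/\tau$ is the mean
lysis time), $B$ the burst size, $r$ and $K$ the bacterial growth rate
and carrying capacity, and $\delta$ the chemostat dilution rate. Summing
over strains recovers the aggregate system in which the lysogenization
and reactivation rates are the population means
$\bar\phi = q\,\phi_m + (1-q)\,\phi_w$ and
$\bar\alpha = p\,\alpha_m + (1-p)\,\alpha_w$, with $q$ and $p$ the mutant
frequencies among virions and lysogens. We integrate the strain-resolved
seven-compartment form rather than the aggregate-plus-frequency form
because frequency ODEs degenerate (0/0) whenever a compartment empties;
frequencies are always derived from densities after the fact.

Key modelling assumptions: no superinfection or coinfection (prophage
carriage confers immunity), no resistant bacteria, perfect vertical
transmission, no cost of prophage carriage on host growth, exponentially
distributed lysis times (a single $Y$ stage), and purely deterministic
dynamics — the chemostat populations are large enough that demographic
stochasticity is negligible, so all variability in data is treated as
measurement error.

The package also implements the nested "instantaneous lysis" variant
(`simulate_original_model()`), in which the $Y$ stage is removed and
lytic events release $B$ virions immediately. The lysis delay is the only
structural difference, which is what makes the AIC comparison between the
two variants (`compare_models()`) a clean test of whether the data carry
a signature of the delay. In the delayed model the mutant frequency among
infected cells $g$ shows a transient overshoot during the acute epidemic
phase — driven by the $Y$ cells — that the instantaneous variant cannot
produce.

## Observables

Experiments measure, per chemostat and hour: the prevalence
$P = 1 - S/N$, the mutant frequency among infected cells
$g = (Y_m + L_m)/(Y + L)$, and the mutant frequency among free virions
$q$. All three are analysed on the log-odds (logit) scale. Frequencies
with empty denominators (for instance $f = Y_m/Y$ at $t = 0$, when only
lysogens have been introduced) are undefined and reported as `NaN`;
sampling grids therefore start at $t = 1$ h, after the system has entered
its early dynamical regime.

## Closed-form theory

Three results anchor the inference:

* **Invasion threshold.** A strain introduced into a fully susceptible
  population of density $S_0$ invades iff its basic reproduction number
  (`basic_reproduction_number()`) exceeds 1. With
  $A = r(1-\tfrac{S_0}{K})(aS_0+\delta)(\tau+\delta) +
  a b S_0 \tau B(\alpha_k + (1-\phi_k)\delta)$,
  $$\mathcal R_{0,k} = \frac{A + \sqrt{A^2 - 4r(1-\tfrac{S_0}{K})(1-\phi_k)
  \, a b S_0 \tau B\,(aS_0+\delta)(\alpha_k+\delta)(\tau+\delta)}}
  {2(aS_0+\delta)(\alpha_k+\delta)(\tau+\delta)}.$$
  The default $S_0 = K$ matches an experiment started at carrying
  capacity, where the growth term vanishes and only the horizontal route
  remains. The square root makes the expression formally sensitive to
  rounding when the discriminant is near zero, so a guard clamps values
  within $-10^{-12}$ of zero. The test suite verifies, over random
  parameter draws, that $\mathcal R_0 = 1$ coincides exactly with the
  loss of stability of the virus-free state (dominant eigenvalue of the
  linearized infection subsystem), which is an independent derivation of
  the same threshold.

* **Selection gradients.** The selection gradient is the rate of change
  of the mutant's logit frequency. At the onset of an epidemic with
  abundant susceptibles the lytic route dominates and the gradient is
  proportional to $-\Delta\phi = \phi_w - \phi_m$; the proportionality
  constant depends on the epidemic growth rate and is not asserted —
  `onset_gradient_check()` instead measures the logit-$f$ slope of a
  constant-$S$ simulation (the susceptible density pinned), and the tests
  assert sign and proportionality across parameter pairs. Fit windows
  default to $[1, 3]$ h because the approximation needs the fast initial
  transient to have passed but the susceptible pool to still be intact.
  At the end of the epidemic no susceptibles remain, lysogens dominate,
  and the gradient is exactly $-\Delta\alpha = \alpha_w - \alpha_m$
  (`endemic_selection_gradient()`); slope fits use the last third of the
  trajectory by default.

* **Differentiation between life stages.** The odds ratio
  $\mathcal Q^{VL} = \frac{q/(1-q)}{p/(1-p)}$ compares the mutant's
  frequency among virions with that among prophages. At high prevalence
  it converges to approximately $\alpha_m/\alpha_w$; the same value holds
  just after introduction, before any complete infection cycle. Whether
  this convergence is exact or first-order in $\Delta\alpha$ is not
  settled; simulation places it within a few percent of
  $\alpha_m/\alpha_w$ under the study conditions and the tests use a 10%
  band.

## The two-step estimation

Fitting all parameters at once is possible but wasteful, because the two
results above identify the reactivation rates directly.

**Step 1** (`estimate_alphas()`). Per chemostat, data are kept from the
first time the *observed* prevalence reaches 95% (first crossing of the
noisy series, no smoothing — post-crossing points dominate the fit, so
smoothing would add complexity without robustness). A single linear model
of logit $g$ on time with chemostat-specific intercepts and a common
slope gives $\hat{\mathcal S}$; an option fits per-chemostat slopes and
averages them instead, and the two agree closely on clean data. The
differentiation is estimated by the geometric mean of the observed odds
ratio, computed as $\exp(\overline{\mathrm{logit}\,q -
\mathrm{logit}\,g})$ — numerically identical to the product definition
but immune to overflow — substituting the measured $g$ for the
unobserved $p$, which it approaches at high prevalence. Inverting the two
theoretical results yields
$\hat\alpha_w = \hat{\mathcal S}/(1-\hat{\mathcal Q})$ and
$\hat\alpha_m = \hat{\mathcal S}\hat{\mathcal Q}/(1-\hat{\mathcal Q})$.
Estimates with $\hat{\mathcal Q} = 1$ or negative rates are flagged
invalid rather than silently clipped. Only the endemic regime is needed,
so this step works on endemic-treatment data alone. Note that even
noise-free estimates carry a small (~2%) bias from the finite horizon:
$\mathcal Q^{VL}(t)$ has not fully converged to $\alpha_m/\alpha_w$ by
60 h.

**Step 2** (`fit_mle()`). With $\alpha_w$, $\alpha_m$, $K$, $\delta$ and
$B$ fixed, the remaining parameters
$\theta = (\phi_w, \phi_m, a, b, r, \tau, P_0^{\text{epidemic}},
P_0^{\text{endemic}}, p_0)$ are estimated by maximizing a Gaussian
likelihood of the observed logits around the deterministic trajectories,
i.i.d. across treatments, chemostats, times and the three responses.
$B$ is fixed because only the product $b \times B$ is identifiable:
rescaling the (unobserved) virion density maps $(b, B)$ onto
$(cb, B/c)$ without changing any observable, so the profile likelihood
(`profile_bB()`) is flat along contours of constant $b \times B$. The
measurement SDs $\sigma_P, \sigma_g, \sigma_q$ are profiled analytically
(the Gaussian variance MLE given the residuals) inside every likelihood
evaluation, which is equivalent at the optimum to estimating them jointly
and removes three dimensions from the search.

## Numerical choices

* **Integration.** `lsoda` (stiff-capable, automatic switching) with
  relative tolerance $10^{-8}$ and absolute tolerance $10^{-6}$ on
  densities stored internally in units of $K$ — the state spans nine
  orders of magnitude, so the rescaling keeps the absolute tolerance
  meaningful. The right-hand sides are compiled C; a pure-R
  implementation is kept as the reference and the tests assert agreement.
  Undershoots below $-10^{-9} K$ abort the run; smaller ones are clamped
  to zero before observables are formed.
* **Profiled-variance floor.** The profiled SD is floored at $10^{-3}$
  (logit units), one order of magnitude below the smallest measurement SD
  in the simulation study. The logit transform amplifies solver error
  without bound as the prevalence saturates, so residuals below this
  level reflect integration accuracy, not fit quality; without the floor
  a numerically perfect fit has unbounded likelihood and equivalent
  parameter sets become spuriously distinguishable.
* **Bounds and transformations.** Optimization is unconstrained through
  smooth reparameterisations: bounded log-odds for probabilities and
  prevalences, bounded log for positive rates. The default box is
  $\phi_{w,m} \in [10^{-4}, 0.999]$, $a \in [10^{-10}, 10^{-6}]$,
  $b \in [10^{-4}, 0.2]$, $\tau \in [0.1, 10]$, $r \in [0.81, 5]$ (the
  growth rate must exceed the dilution rate for the culture to persist),
  $P_0 \in [10^{-3}, 0.999]$, $p_0 \in [0.01, 0.99]$; every entry is
  overridable (`default_bounds()`).
* **Multi-start policy.** Starting points are drawn uniformly inside the
  box (geometrically for log-scale parameters). Each start is a
  Nelder-Mead run capped at 5000 evaluations with relative tolerance
  $10^{-8}$. Single Nelder-Mead runs in nine dimensions stall routinely
  (simplex degeneracy along curved valleys), so the best candidates —
  the three lowest likelihood values over all starts, whether or not
  their run terminated cleanly — are refined by restarting the simplex
  at its own endpoint until a restart improves the objective by less
  than 0.01 (two orders of magnitude below the AIC-relevant scale of 2).
  Ties among equal-likelihood starts break by lowest start index. A
  failed likelihood evaluation (ODE failure at an extreme parameter set)
  returns $+\infty$ rather than erroring, so the simplex simply moves
  away.
* **Desk scale vs full scale.** The package defaults are desk-scale: 50
  optimization starts and 200 bootstrap replicates. A full-scale analysis
  (2000 starts, 10000 replicates) is a configuration change, not a code
  change.

## Synthetic data

`generate_dataset()` reproduces the structure of the study's simulated
datasets: each treatment (epidemic, initial prevalence 1%; endemic, 99%;
bacteria at carrying capacity, prophage ratio 1:1) is simulated once
deterministically, and i.i.d. Gaussian noise is added per replicate,
response and time point *on the logit scale* — a literal reading of the
measurement-error model, and the scale on which the likelihood operates.
Defaults are 4 chemostats per treatment and hourly sampling over 1–60 h,
with noise SD 0.5 per response, the value closest to the
measurement-error magnitudes estimated from real chemostat data; the
study's data-quality grid (SD 0.5 vs 0.01) and data-quantity grid
(sampling every 10 h vs hourly) are reached by overriding the design.
(Descriptions of the sampling grid disagree between sources — 0.1 vs 1
per hour in one place, 10 per hour in another; the design object accepts
any grid, and package defaults use 1 per hour.) One global seed spawns
one substream per (treatment, replicate, response), so adding replicates
never perturbs existing ones.

What the generator does *not* emulate: FACS/qPCR measurement mechanics,
autocorrelated or non-Gaussian noise, demographic stochasticity,
temperature- or MOI-dependent plasticity of the phage traits, and
between-chemostat parameter heterogeneity. Passing the recovery tests on
these data therefore shows that the estimation machinery is correct and
well-calibrated under the stated error model — not that the model is a
complete description of any real chemostat.

## Sieve bootstrap

Confidence intervals come from a residual bootstrap that respects serial
dependence (`sieve_bootstrap()`): residuals between the data and the
best-fit trajectories are centred per chemostat and response, an ARMA
model (orders selected by corrected AIC over $p, q \le 3$, stationarity
and invertibility enforced, white noise as fallback) is fitted to each
series, and new datasets are rebuilt as fitted trajectory + centring
constant + ARMA-simulated residuals (Gaussian innovations, 50-step
burn-in, original missingness pattern preserved). The full two-step
estimation is then repeated on each bootstrap dataset — step 1 afresh,
step 2 as a single restarted Nelder-Mead refinement from the original
MLE. Replicates failing outright (invalid step-1 estimate, integration
failure) are dropped and counted; budget-limited refinements are kept,
because every refinement starts at the MLE and discarding the slow ones
would bias resampling toward easy datasets. Intervals are equal-tailed
percentile intervals (the CI method is not prescribed by the estimation
theory; percentile is the simplest choice consistent with reporting
joint draws). The bootstrap replicate refinements use a looser relative
tolerance ($10^{-6}$) than the original fit: across-replicate variation,
not optimizer precision, drives the interval widths.

## Problem sizes used by the shipped checks

The package's own test suite and the acceptance script run at desk
scale, chosen so the whole suite completes on a laptop: 50 optimization
starts for the headline recovery check (SD 0.01 data), 8–15 starts for
model comparison and the bootstrap's base fit (SD 0.5 data), 200
bootstrap replicates, and a 3 × 3 grid for the $b \times B$ profile on
noise-free data. These sizes are statements about the shipped checks,
not limits of the implementation.

## Known limitations

* The onset approximation is useful only while susceptibles remain
  effectively constant; in a real epidemic that window is short, and the
  package deliberately reports only proportionality in $-\Delta\phi$.
* The adsorption rate $a$ and growth rate $r$ are weakly identified by
  this experimental design; their recovery is not asserted anywhere, and
  `sensitivity_scan()` exists precisely to quantify how little the other
  estimates depend on them.
* Percentile intervals inherit the usual caveat that they undercover
  when the estimator is biased; the step-1 finite-horizon bias (~2%) is
  small but not zero.
* The instantaneous-lysis variant shares every assumption except the
  lysis delay, so the AIC comparison says nothing about assumptions the
  two models share (e.g. no superinfection).
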