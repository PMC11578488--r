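# Example phagevo pipeline configuration (desk scale).
# All values shown are the defaults of phagevo::default_config();
# any subset may be overridden.
params:
  alpha_w: 7.0e-3     # wildtype prophage reactivation rate (1/h)
  alpha_m: 2.0e-2     # mutant reactivation rate (1/h)
  phi_w: 0.2          # wildtype lysogenization probability
  phi_m: 2.0e-2       # mutant lysogenization probability
  a: 3.0e-9           # adsorption rate (1/h/cell)
  b: 0.1              # fusion probability
  B: 80.0             # burst size (virions/cell)
  r: 1.4              # bacterial growth rate (1/h)
  tau: 1.5            # lysis rate (1/h)
  K: 1.0e+9           # carrying capacity (cells)
  delta: 0.8          # chemostat dilution rate (1/h)
design:
  treatments:
    epidemic: 0.01    # initial prevalence per treatment
    endemic: 0.99
  replicates: 4
  t_min: 1.0          # sampling grid (hours)
  t_max: 60.0
  t_step: 1.0
  sigma_P: 0.5        # measurement-error SD, logit prevalence
  sigma_g: 0.5        # ... logit infected mutant frequency
  sigma_q: 0.5        # ... logit free-virus mutant frequency
  mutant_share: 0.5   # initial mutant share among lysogens
  seed: 1
inference:
  n_starts: 8         # Nelder-Mead starting points (2000 = full scale)
  seed: 1
  prevalence_threshold: 0.95
  bounds: {}          # optional per-parameter [lo, hi] overrides
bootstrap:
  n_boot: 20          # bootstrap datasets (10000 = full scale)
  seed: 1
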