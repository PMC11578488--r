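# Shared fixtures. Heavy objects (datasets, fits) are built once per test
# run and cached, so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

truth_theta <- function() {
  list(phi_w = 0.2, phi_m = 0.02, a = 3e-9, b = 0.1, r = 1.4, tau = 1.5,
       P0_epidemic = 0.01, P0_endemic = 0.99, p0 = 0.5)
}

fixed_at <- function(alpha_w = 7e-3, alpha_m = 2e-2) {
  list(K = 1e9, delta = 0.8, B = 80, alpha_w = alpha_w, alpha_m = alpha_m)
}

# High-quality study dataset: both treatments, 4 chemostats, hourly
# sampling 1-60 h, measurement SD 0.01 on all three logit responses.
hq_dataset <- function() {
  cached("hq_dataset", generate_dataset(
    default_params(),
    design_spec(sigma_P = 0.01, sigma_g = 0.01, sigma_q = 0.01),
    seed = 101))
}

hq_alphas <- function() cached("hq_alphas", estimate_alphas(hq_dataset()))

# The full two-step fit on the high-quality dataset (50 uniform starts).
hq_fit <- function() {
  cached("hq_fit", {
    a <- hq_alphas()
    fit_mle(hq_dataset(), fixed_at(a$alpha_w, a$alpha_m),
            n_starts = 50L, seed = 202)
  })
}

# Realistic-noise dataset (measurement SD 0.5, the generator default).
sd5_dataset <- function() {
  cached("sd5_dataset", generate_dataset(default_params(), design_spec(),
                                         seed = 55))
}

sd5_alphas <- function() cached("sd5_alphas", estimate_alphas(sd5_dataset()))

sd5_fit <- function() {
  cached("sd5_fit", {
    a <- sd5_alphas()
    fit_mle(sd5_dataset(), fixed_at(a$alpha_w, a$alpha_m),
            n_starts = 15L, seed = 31)
  })
}

# Noise-free dataset: replicates coincide with the deterministic logits.
noise_free_dataset <- function() {
  cached("noise_free_dataset", generate_dataset(
    default_params(),
    design_spec(sigma_P = 0, sigma_g = 0, sigma_q = 0, replicates = 2L),
    seed = 1))
}

# Small coarse dataset for cheap optimizer tests.
coarse_dataset <- function() {
  cached("coarse_dataset", generate_dataset(
    default_params(),
    design_spec(times = seq(1, 60, by = 5), replicates = 2L,
                sigma_P = 0.3, sigma_g = 0.3, sigma_q = 0.3),
    seed = 17))
}
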