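# A hand-built endemic dataset with exact logit-g slope and constant
# log odds-ratio, for which the step-1 formulas can be inverted by hand.
constructed_dataset <- function(slope = -0.013, logQ = log(20 / 7),
                                chemostats = 1:2, times = 1:60) {
  rows <- lapply(chemostats, function(ch) {
    lg <- -1 + slope * times + 0.05 * ch  # chemostat-specific intercept
    data.frame(treatment = "endemic", chemostat = ch, time_h = times,
               logit_P = 4, logit_g = lg, logit_q = lg + logQ)
  })
  d <- do.call(rbind, rows)
  class(d) <- c("phage_dataset", "data.frame")
  d
}

test_that("step-1 formulas invert exactly on a constructed dataset", {
  est <- estimate_alphas(constructed_dataset())
  expect_equal(est$S_hat, -0.013, tolerance = 1e-10)
  expect_equal(est$Q_hat, 20 / 7, tolerance = 1e-10)
  expect_equal(est$alpha_w, 7e-3, tolerance = 1e-10)
  expect_equal(est$alpha_m, 2e-2, tolerance = 1e-10)
  expect_true(est$valid)
})

test_that("step-1 estimates recover the generating rates from clean data", {
  # the residual ~2% bias is the finite-horizon convergence of the
  # differentiation towards alpha_m/alpha_w, not estimation noise
  est <- estimate_alphas(noise_free_dataset())
  expect_equal(est$alpha_w, 7e-3, tolerance = 0.05)
  expect_equal(est$alpha_m, 2e-2, tolerance = 0.05)
  # per-chemostat slope variant agrees on clean data
  est2 <- estimate_alphas(noise_free_dataset(), method = "per_chemostat")
  expect_equal(est2$alpha_w, est$alpha_w, tolerance = 1e-2)
})

test_that("step-1 error decreases as measurement noise shrinks", {
  p <- default_params()
  # noise-induced error is measured against the zero-noise limit of the
  # estimator (which carries the small finite-horizon bias)
  limit <- estimate_alphas(noise_free_dataset())$alpha_w
  for (seed in 11:13) {
    err <- vapply(c(0.5, 0.1, 0.01), function(s) {
      d <- generate_dataset(p, design_spec(sigma_P = s, sigma_g = s,
                                           sigma_q = s), seed = seed)
      abs(estimate_alphas(d)$alpha_w - limit)
    }, numeric(1))
    expect_true(all(diff(err) < 0))
  }
})

test_that("step-1 is invariant to relabelling and pre-threshold points", {
  d <- constructed_dataset()
  ref <- estimate_alphas(d)
  relab <- d
  relab$chemostat <- 3 - relab$chemostat  # swap 1 <-> 2
  est <- estimate_alphas(relab)
  expect_equal(est$alpha_w, ref$alpha_w, tolerance = 1e-12)
  # prepend low-prevalence points: first crossing unchanged
  pre <- constructed_dataset(times = -9:0 + 0)
  pre$time_h <- pre$time_h + 0  # times -9..0 h
  pre$logit_P <- -3              # prevalence far below threshold
  both <- rbind(pre, d)
  class(both) <- c("phage_dataset", "data.frame")
  est2 <- estimate_alphas(both)
  expect_equal(est2$alpha_w, ref$alpha_w, tolerance = 1e-12)
  expect_equal(est2$n_points, ref$n_points)
})

test_that("step-1 flags degenerate differentiation and missing crossings", {
  d <- constructed_dataset(logQ = 0)  # g and q coincide -> Q = 1
  est <- estimate_alphas(d)
  expect_false(est$valid)
  expect_true(is.na(est$alpha_w))
  low <- constructed_dataset()
  low$logit_P <- 0  # prevalence never reaches 95%
  expect_error(estimate_alphas(low), "threshold")
  expect_error(estimate_alphas(constructed_dataset(), 1.5), "\\(0, 1\\)")
})

test_that("the likelihood matches its closed form at zero residuals", {
  d <- noise_free_dataset()
  fx <- fixed_at()
  nll <- negative_log_likelihood(truth_theta(), d, fx,
                                 sigmas = c(P = 1, g = 1, q = 1))
  parts <- attr(nll, "parts")
  # residuals are numerically zero, sigma = 1: each point contributes
  # log(2 pi)/2
  ns <- vapply(c("logit_P", "logit_g", "logit_q"),
               function(v) sum(is.finite(d[[v]])), numeric(1))
  expect_equal(unname(parts),
               unname(ns) / 2 * log(2 * pi), tolerance = 1e-6)
  expect_equal(as.numeric(nll), sum(parts))
})

test_that("the profiled sigma is the residual RMS and minimises the likelihood", {
  d <- coarse_dataset()
  fx <- fixed_at()
  nll_prof <- negative_log_likelihood(truth_theta(), d, fx)
  sig <- attr(nll_prof, "sigmas")
  # profiled value beats nearby fixed sigmas
  for (f in c(0.8, 1.25)) {
    worse <- negative_log_likelihood(truth_theta(), d, fx,
                                     sigmas = sig * f)
    expect_gt(as.numeric(worse), as.numeric(nll_prof))
  }
  # and equals the likelihood evaluated at the profiled sigmas
  same <- negative_log_likelihood(truth_theta(), d, fx, sigmas = sig)
  expect_equal(as.numeric(same), as.numeric(nll_prof), tolerance = 1e-9)
})

test_that("the generating parameters beat random perturbations on clean data", {
  d <- hq_dataset()
  fx <- fixed_at()
  ref <- as.numeric(negative_log_likelihood(truth_theta(), d, fx))
  set.seed(5)
  for (i in 1:20) {
    th <- truth_theta()
    for (nm in c("phi_w", "phi_m", "a", "b", "r", "tau"))
      th[[nm]] <- th[[nm]] * runif(1, 0.8, 1.2)
    th$p0 <- min(0.99, th$p0 * runif(1, 0.8, 1.2))
    expect_gt(as.numeric(negative_log_likelihood(th, d, fx)), ref)
  }
})

test_that("the likelihood penalises an integration failure instead of erroring", {
  d <- coarse_dataset()
  th <- truth_theta()
  th$P0_epidemic <- NA_real_
  expect_identical(negative_log_likelihood(th, d, fixed_at()), Inf)
  expect_error(negative_log_likelihood(truth_theta(), d, list(K = 1e9)),
               "fixed")
})

test_that("the optimizer is deterministic given a seed", {
  d <- coarse_dataset()
  a <- estimate_alphas(d)
  fx <- fixed_at(a$alpha_w, a$alpha_m)
  f1 <- fit_mle(d, fx, n_starts = 2L, seed = 99)
  f2 <- fit_mle(d, fx, n_starts = 2L, seed = 99)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$nll, f2$nll)
  expect_identical(f1$diagnostics, f2$diagnostics)
})

test_that("bound transformations honour the box and reject bad overrides", {
  b <- default_bounds()
  expect_setequal(
    b$param,
    c("phi_w", "phi_m", "a", "b", "r", "tau", "P0_epidemic",
      "P0_endemic", "p0"))
  expect_error(default_bounds(overrides = list(zeta = c(0, 1))), "unknown")
  expect_error(default_bounds(overrides = list(tau = c(5, 1))), "lo < hi")
  bb <- default_bounds(overrides = list(tau = c(0.5, 4)))
  expect_equal(bb$hi[bb$param == "tau"], 4)
})

test_that("a scan over a single reference value reproduces the reference fit", {
  fit <- sd5_fit()
  scan <- sensitivity_scan(sd5_dataset(), fit, "B", values = 80)
  expect_equal(scan$phi_w, fit$theta$phi_w, tolerance = 0.02)
  expect_lt(max(abs(scan[, startsWith(names(scan), "rel_")])), 0.05)
  expect_error(sensitivity_scan(sd5_dataset(), fit, "K", 1), "free")
})

test_that("estimates are robust to the fixed burst size except through b", {
  fit <- sd5_fit()
  scan <- sensitivity_scan(sd5_dataset(), fit, "B", values = c(40, 160))
  # compensation: b moves so that b x B is conserved
  prod_ref <- fit$theta$b * 80
  expect_equal(scan$b * scan$value, rep(prod_ref, 2), tolerance = 0.1)
  # the other phage parameters barely move
  for (nm in c("rel_phi_w", "rel_phi_m", "rel_tau"))
    expect_lt(max(abs(scan[[nm]])), 0.25)
  # and R0 is invariant to the choice of B
  r0 <- vapply(seq_len(nrow(scan)), function(i) {
    pp <- default_params(alpha_w = fit$fixed$alpha_w,
                         alpha_m = fit$fixed$alpha_m,
                         phi_w = scan$phi_w[i], phi_m = scan$phi_m[i],
                         a = scan$a[i], b = scan$b[i], r = scan$r[i],
                         tau = scan$tau[i], B = scan$value[i])
    basic_reproduction_number(pp, "w")$R0
  }, numeric(1))
  ref_params <- default_params(alpha_w = fit$fixed$alpha_w,
                               alpha_m = fit$fixed$alpha_m,
                               phi_w = fit$theta$phi_w,
                               phi_m = fit$theta$phi_m, a = fit$theta$a,
                               b = fit$theta$b, r = fit$theta$r,
                               tau = fit$theta$tau, B = 80)
  expect_equal(r0, rep(basic_reproduction_number(ref_params, "w")$R0, 2),
               tolerance = 0.05)
})
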