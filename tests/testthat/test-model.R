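test_that("virus-free equilibrium is a fixed point of the dynamics", {
  p <- default_params()
  st <- state_vector(S = virus_free_equilibrium(p))
  expect_equal(max(abs(derivatives(st, p))), 0)
  # and the trajectory started there stays there
  tr <- simulate_model(p, st, times = 0:20)
  expect_lt(max(abs(tr$S - tr$S[1])) / tr$S[1], 1e-8)
  expect_equal(max(tr$V_w + tr$V_m), 0)
})

test_that("lysogen-only dynamics at S = 0 have no infection terms", {
  p <- default_params()
  st <- state_vector(S = 0, L_w = 2e8, L_m = 1e8)
  d <- derivatives(st, p)
  N <- 3e8
  grow <- p$shared$r * (1 - N / p$shared$K)
  expect_equal(d[["L_w"]],
               grow * 2e8 - (p$wildtype$alpha + p$shared$delta) * 2e8)
  expect_equal(d[["L_m"]],
               grow * 1e8 - (p$mutant$alpha + p$shared$delta) * 1e8)
  expect_equal(d[["S"]], 0)
})

test_that("symmetric strains give symmetric derivatives", {
  p <- default_params(alpha_m = 7e-3, phi_m = 0.2)
  st <- state_vector(S = 4e8, L_w = 1e8, L_m = 1e8, Y_w = 3e7, Y_m = 3e7,
                     V_w = 2e8, V_m = 2e8)
  d <- derivatives(st, p)
  expect_equal(d[["L_w"]], d[["L_m"]])
  expect_equal(d[["Y_w"]], d[["Y_m"]])
  expect_equal(d[["V_w"]], d[["V_m"]])
})

test_that("derivatives reject invalid input", {
  p <- default_params()
  expect_error(derivatives(c(S = NA, L_w = 0, L_m = 0, Y_w = 0, Y_m = 0,
                             V_w = 0, V_m = 0), p), "finite")
  expect_error(derivatives(state_vector(S = 1), "not params"))
  expect_error(state_vector(S = -1), "non-negative")
})

test_that("strain-resolved derivatives aggregate to the mean-trait form", {
  p <- default_params()
  pv <- c(a = p$shared$a, b = p$shared$b, tau = p$shared$tau,
          B = p$shared$B, r = p$shared$r, K = p$shared$K,
          delta = p$shared$delta)
  set.seed(42)
  for (i in 1:1000) {
    y <- runif(7, 0, 1) * c(1e9, 1e9, 1e9, 1e8, 1e8, 1e10, 1e10)
    names(y) <- c("S", "L_w", "L_m", "Y_w", "Y_m", "V_w", "V_m")
    d <- derivatives(y, p)
    L <- y[["L_w"]] + y[["L_m"]]
    Y <- y[["Y_w"]] + y[["Y_m"]]
    V <- y[["V_w"]] + y[["V_m"]]
    N <- y[["S"]] + L + Y
    q <- y[["V_m"]] / V
    pfreq <- y[["L_m"]] / L
    mt <- mean_traits(q, pfreq, p)
    grow <- pv[["r"]] * (1 - N / pv[["K"]])
    foi <- pv[["a"]] * pv[["b"]] * V * y[["S"]]
    # aggregate equations with population-mean traits
    expect_equal(d[["L_w"]] + d[["L_m"]],
                 grow * L + mt[["phi_bar"]] * foi -
                   mt[["alpha_bar"]] * L - pv[["delta"]] * L,
                 tolerance = 1e-12)
    expect_equal(d[["Y_w"]] + d[["Y_m"]],
                 (1 - mt[["phi_bar"]]) * foi + mt[["alpha_bar"]] * L -
                   (pv[["tau"]] + pv[["delta"]]) * Y,
                 tolerance = 1e-12)
    expect_equal(d[["V_w"]] + d[["V_m"]],
                 pv[["tau"]] * Y * pv[["B"]] - pv[["a"]] * N * V -
                   pv[["delta"]] * V,
                 tolerance = 1e-12)
  }
})

test_that("mean traits are convex combinations with the right endpoints", {
  p <- default_params()
  expect_equal(mean_traits(0, 0, p)[["phi_bar"]], p$wildtype$phi)
  expect_equal(unname(mean_traits(1, 1, p)),
               c(p$mutant$phi, p$mutant$alpha))
  expect_equal(mean_traits(0.5, 0.5, p)[["phi_bar"]], 0.11)
  expect_error(mean_traits(1.2, 0.5, p), "frequencies")
})

test_that("initial_state lays out the experimental initial conditions", {
  p <- default_params()
  st <- initial_state(0.01, 0.5, p)
  expect_equal(st[["S"]], 9.9e8)
  expect_equal(st[["L_w"]], 5e6)
  expect_equal(st[["L_m"]], 5e6)
  expect_equal(sum(st[c("Y_w", "Y_m", "V_w", "V_m")]), 0)
  expect_equal(initial_state(0, 0.5, p)[["S"]], 1e9)
  st2 <- initial_state(1, 1, p)
  expect_equal(st2[["S"]], 0)
  expect_equal(st2[["L_m"]], 1e9)
  expect_error(initial_state(1.5, 0.5, p), "prevalence")
})

test_that("the frequency of infected cells is the Y/L-weighted mean", {
  p <- default_params()
  tr <- simulate_model(p, initial_state(0.01, 0.5, p), 0:40)
  keep <- tr$time > 0
  Y <- tr$Y_w + tr$Y_m
  L <- tr$L_w + tr$L_m
  expect_equal(tr$g[keep],
               (tr$f * Y / (Y + L) + tr$p * L / (Y + L))[keep],
               tolerance = 1e-12)
})

test_that("a neutral variant stays at frequency one half everywhere", {
  p <- default_params(alpha_m = 7e-3, phi_m = 0.2)
  tr <- simulate_model(p, initial_state(0.1, 0.5, p), 0:50)
  keep <- tr$time > 0
  for (v in c("p", "q", "f", "g"))
    expect_equal(tr[[v]][keep], rep(0.5, sum(keep)), tolerance = 1e-9)
})

test_that("in the pure-dilution limit bacteria wash out as exp(-delta t)", {
  # no growth, no adsorption, no reactivation: dilution is the only flow
  p <- default_params(r = 0, a = 0, alpha_w = 0, alpha_m = 0)
  tr <- simulate_model(p, initial_state(0.3, 0.5, p), 0:10)
  N <- tr$S + tr$L_w + tr$L_m + tr$Y_w + tr$Y_m
  # tolerance reflects the solver's absolute tolerance (1e-6 K) relative
  # to the washed-out densities at late times
  expect_equal(N / N[1], exp(-p$shared$delta * tr$time), tolerance = 1e-3)
})

test_that("compiled and pure-R right-hand sides integrate identically", {
  p <- default_params()
  init <- initial_state(0.01, 0.5, p)
  a <- simulate_model(p, init, 0:30, use_compiled = TRUE)
  b <- simulate_model(p, init, 0:30, use_compiled = FALSE)
  expect_equal(as.matrix(a[, 2:8]), as.matrix(b[, 2:8]),
               tolerance = 1e-7)
  ai <- simulate_original_model(p, init, 0:30, use_compiled = TRUE)
  bi <- simulate_original_model(p, init, 0:30, use_compiled = FALSE)
  expect_equal(as.matrix(ai[, 2:6]), as.matrix(bi[, 2:6]),
               tolerance = 1e-7)
})

test_that("an epidemic started small saturates at full prevalence", {
  p <- default_params()
  tr <- simulate_model(p, initial_state(0.01, 0.5, p), 0:60)
  expect_gt(tr$P[tr$time == 60], 0.98)
  expect_true(all(diff(tr$P[tr$time >= 2 & tr$time <= 20]) > 0))
})

test_that("without fusion the virus dies out and bacteria reach K(1 - delta/r)", {
  # at b = 0 the vertical-only reproduction number is delta/(alpha + delta),
  # just below 1, so extinction is slow: check the trend on a long horizon
  p <- default_params(b = 0)
  tr <- simulate_model(p, initial_state(0.01, 0.5, p), seq(0, 400, 5))
  V <- tr$V_w + tr$V_m
  expect_lt(V[length(V)], max(V) / 10)
  expect_true(all(diff(tail(V, 20)) < 0))
  expect_equal(tr$S[nrow(tr)], virus_free_equilibrium(p),
               tolerance = 1e-2)
})

test_that("integration rejects a malformed time grid or initial state", {
  p <- default_params()
  init <- initial_state(0.01, 0.5, p)
  expect_error(simulate_model(p, init, c(0, 0, 1)), "increasing")
  expect_error(simulate_model(p, init, 5), "increasing")
  expect_error(
    simulate_original_model(p, state_vector(S = 1e9, Y_w = 1), 0:10),
    "Y compartment")
})

test_that("constant-S onset dynamics favour the lysis-prone mutant", {
  p <- default_params()
  g <- onset_gradient_check(p)
  expect_gt(g$gradient, 0)
  # neutral variant: flat logit-f
  g0 <- onset_gradient_check(default_params(alpha_m = 7e-3, phi_m = 0.2))
  expect_lt(abs(g0$gradient), 1e-6)
  expect_error(onset_gradient_check(p, window = c(0, 2)), "t >= 1")
})

test_that("the early logit-f slope is proportional to the lysogeny deficit", {
  # equal reactivation rates isolate the lysogenization difference
  slope1 <- onset_gradient_check(
    default_params(alpha_m = 7e-3, phi_w = 0.2, phi_m = 0.1))$gradient
  slope2 <- onset_gradient_check(
    default_params(alpha_m = 7e-3, phi_w = 0.2, phi_m = 0.15))$gradient
  expect_equal(slope1 / slope2, 2, tolerance = 0.1)
})

test_that("the instantaneous-lysis limit is recovered as tau grows", {
  sup <- vapply(c(10, 100, 1000), function(tv) {
    p <- default_params(tau = tv)
    init <- initial_state(0.01, 0.5, p)
    a <- simulate_model(p, init, 0:30)
    b <- simulate_original_model(p, init, 0:30)
    max(abs(a$S - b$S),
        abs((a$L_w + a$L_m) - (b$L_w + b$L_m)),
        abs((a$V_w + a$V_m) - (b$V_w + b$V_m))) / p$shared$K
  }, numeric(1))
  expect_true(all(diff(sup) < 0))
  expect_lt(sup[3], 1)
})

test_that("only the delayed-lysis model shows the transient overshoot in g", {
  p <- default_params()
  init <- initial_state(0.01, 0.5, p)
  gd <- simulate_model(p, init, seq(0, 60, 0.5))$g
  gi <- simulate_original_model(p, init, seq(0, 60, 0.5))$g
  expect_gt(max(gd, na.rm = TRUE), max(gi, na.rm = TRUE) + 0.1)
})

test_that("trajectories round-trip through the tidy CSV export", {
  p <- default_params()
  tr <- simulate_model(p, initial_state(0.5, 0.5, p), 0:5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read.csv(path)
  expect_identical(names(back),
                   c("time", "S", "L_w", "L_m", "Y_w", "Y_m", "V_w", "V_m",
                     "P", "p", "q", "f", "g"))
  expect_equal(back$S, tr$S, tolerance = 1e-12)
})
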