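test_that("R0 at S0 = K reduces to the purely horizontal closed form", {
  p <- default_params()
  s <- p$shared
  for (strain in c("wildtype", "mutant")) {
    alpha <- p[[strain]]$alpha
    phi <- p[[strain]]$phi
    # independent route: the S0 = K reduction evaluated directly
    expected <- s$a * s$b * s$K * s$tau * s$B *
      (alpha + (1 - phi) * s$delta) /
      ((s$a * s$K + s$delta) * (alpha + s$delta) * (s$tau + s$delta))
    expect_equal(basic_reproduction_number(p, strain)$R0, expected,
                 tolerance = 1e-12)
  }
})

test_that("R0 without fusion collapses to the vertical-transmission ratio", {
  p <- default_params(b = 0)
  S0 <- 5e8
  r0 <- basic_reproduction_number(p, "w", S0 = S0)
  expect_equal(r0$R0,
               p$shared$r * (1 - S0 / p$shared$K) /
                 (p$wildtype$alpha + p$shared$delta),
               tolerance = 1e-12)
  expect_equal(basic_reproduction_number(p, "w")$R0, 0)
  expect_error(basic_reproduction_number(p, "w", S0 = 2e9), "S0")
})

test_that("the virus-free equilibrium follows K(1 - delta/r)", {
  expect_equal(virus_free_equilibrium(default_params()),
               1e9 * (1 - 0.8 / 1.4), tolerance = 1e-12)
  expect_equal(virus_free_equilibrium(default_params(delta = 0)), 1e9)
  expect_error(virus_free_equilibrium(default_params(r = 0.8)), "washout")
  expect_error(virus_free_equilibrium(default_params(r = 0.5)), "washout")
})

test_that("R0 = 1 coincides with loss of stability of the virus-free state", {
  # independent oracle: a strain invades at frozen susceptible density S0
  # iff the dominant eigenvalue of its linearized (L, Y, V) infection
  # subsystem is positive
  infection_jacobian <- function(p, strain, S0) {
    s <- p$shared
    alpha <- p[[strain]]$alpha
    phi <- p[[strain]]$phi
    g0 <- s$r * (1 - S0 / s$K)
    abS <- s$a * s$b * S0
    matrix(c(g0 - alpha - s$delta, 0,                 phi * abS,
             alpha,                -(s$tau + s$delta), (1 - phi) * abS,
             0,                    s$tau * s$B,       -(s$a * S0 + s$delta)),
           3, 3, byrow = TRUE)
  }
  set.seed(7)
  n_checked <- 0
  for (i in 1:200) {
    p <- default_params(
      a = 10^runif(1, -9.5, -8),
      b = runif(1, 0.01, 0.2),
      tau = runif(1, 0.5, 5),
      B = runif(1, 10, 150),
      r = runif(1, 0.9, 3),
      alpha_w = 10^runif(1, -3, -1.3),
      alpha_m = 10^runif(1, -3, -1.3),
      phi_w = runif(1, 0.01, 0.9),
      phi_m = runif(1, 0.01, 0.9))
    S0 <- runif(1, 0.3, 1) * 1e9
    for (strain in c("wildtype", "mutant")) {
      r0 <- basic_reproduction_number(p, strain, S0 = S0)$R0
      expect_true(is.finite(r0))
      if (abs(r0 - 1) <= 1e-6) next
      n_checked <- n_checked + 1
      lambda <- max(Re(eigen(infection_jacobian(p, strain, S0),
                             only.values = TRUE)$values))
      expect_identical(lambda > 0, r0 > 1)
    }
  }
  expect_gt(n_checked, 350)
})

test_that("an above-threshold epidemic grows where a sub-threshold one fades", {
  p <- default_params()  # R0 well above 1 for both strains
  expect_gt(basic_reproduction_number(p, "mutant")$R0, 1)
  tr <- simulate_model(p, initial_state(0.005, 0.5, p), 0:30)
  expect_gt(tr$P[nrow(tr)], 0.5)
  # scaling fusion down pushes R0 below 1: infected pool decays
  plo <- default_params(b = 1e-3, alpha_w = 5e-2, alpha_m = 5e-2, r = 1)
  expect_lt(max(basic_reproduction_number(plo, "w")$R0,
                basic_reproduction_number(plo, "m")$R0), 0.95)
  trlo <- simulate_model(plo, initial_state(0.005, 0.5, plo),
                         seq(0, 100, 2))
  infected <- trlo$L_w + trlo$L_m + trlo$Y_w + trlo$Y_m
  expect_lt(infected[trlo$time == 100], infected[trlo$time == 20] / 5)
})

test_that("the endemic selection gradient is minus the reactivation difference", {
  g <- endemic_selection_gradient(default_params())
  expect_equal(g$gradient, -1.3e-2)
  expect_equal(
    endemic_selection_gradient(default_params(alpha_m = 7e-3))$gradient, 0)
})

test_that("endemic logit frequencies decline linearly with a common slope", {
  p <- default_params()
  tr <- simulate_model(p, initial_state(0.99, 0.5, p), 0:60)
  slopes <- vapply(c("p", "q", "g"), function(v)
    tail_slope(tr$time, logit(tr[[v]])), numeric(1))
  expect_lt(diff(range(slopes)) / abs(mean(slopes)), 0.02)
  expect_equal(mean(slopes), endemic_selection_gradient(p)$gradient,
               tolerance = 0.02)
})

test_that("differentiation is the odds ratio between life stages", {
  expect_equal(differentiation(0.5, 0.5)$Q, 1)
  expect_equal(differentiation(0.8, 0.5)$Q, 4)
  expect_equal(differentiation(0.5, 0.8)$Q, 0.25)
  expect_equal(differentiation(0.8, 0.5)$log_Q,
               -differentiation(0.5, 0.8)$log_Q)
  expect_error(differentiation(1, 0.5), "odds")
  expect_error(differentiation(0.5, 0), "odds")
})

test_that("predicted virion-lysogen differentiation is the reactivation ratio", {
  expect_equal(predicted_differentiation(default_params())$Q, 2e-2 / 7e-3)
  expect_equal(predicted_differentiation(default_params(alpha_m = 7e-3))$Q, 1)
  expect_error(predicted_differentiation(default_params(alpha_w = 0)),
               "alpha_w")
})

test_that("simulated differentiation matches the reactivation ratio at both ends", {
  p <- default_params()
  target <- predicted_differentiation(p)$Q
  tr <- simulate_model(p, initial_state(0.99, 0.5, p),
                       c(0, 0.5, 0.75, 1, seq(5, 60, 5)))
  # early window: no complete infection cycle yet
  early <- tr$time %in% c(0.5, 0.75, 1)
  for (Q in mapply(function(q, pp) differentiation(q, pp)$Q,
                   tr$q[early], tr$p[early]))
    expect_equal(Q, target, tolerance = 0.1)
  # long-run convergence
  expect_equal(differentiation(tr$q[nrow(tr)], tr$p[nrow(tr)])$Q, target,
               tolerance = 0.1)
  # and virions vs Y cells barely differentiate at the end
  expect_lt(abs(differentiation(tr$q[nrow(tr)], tr$f[nrow(tr)])$log_Q),
            0.05)
})
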