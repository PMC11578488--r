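#' Virus-free equilibrium of the bacterial population
#'
#' Without virus, the logistic chemostat converges (when \code{r > delta}) to
#' `S = K (1 - delta/r)`. When \code{r <= delta} the dilution washes the
#' culture out and no positive equilibrium exists.
#'
#' @param params a [model_params()] object.
#' @return The equilibrium susceptible density (cells).
#' @export
virus_free_equilibrium <- function(params) {
  stopifnot(inherits(params, "model_params"))
  s <- params$shared
  if (s$r <= s$delta)
    stop("washout: r <= delta, the bacterial population has no positive ",
         "equilibrium", call. = FALSE)
  s$K * (1 - s$delta / s$r)
}

#' Basic reproduction number of a phage strain
#'
#' Expected number of secondary infections caused by one infected unit of
#' strain `k` introduced into a fully susceptible population of density
#' `S0`. With
#' `A = r (1 - S0/K) (a S0 + delta) (tau + delta) +
#'  a b S0 tau B (alpha_k + (1 - phi_k) delta)`,
#' the reproduction number is
#' `R0 = (A + sqrt(A^2 - 4 r (1 - S0/K) (1 - phi_k) a b S0 tau B
#'  (a S0 + delta) (alpha_k + delta) (tau + delta))) /
#'  (2 (a S0 + delta) (alpha_k + delta) (tau + delta))`.
#' At `S0 = K` the logistic growth term vanishes and the expression
#' reduces to the purely horizontal
#' `a b S0 tau B (alpha_k + (1 - phi_k) delta) /
#'  ((a S0 + delta) (alpha_k + delta) (tau + delta))`.
#' An epidemic breaks out iff `R0 > 1`.
#'
#' @param params a [model_params()] object.
#' @param strain `"wildtype"` (`"w"`) or `"mutant"` (`"m"`).
#' @param S0 initial susceptible density; defaults to `K`, matching an
#'   experiment started at carrying capacity.
#' @return An object of class `r0_result`: list with `strain`, `R0`, `S0`
#'   and the intermediate `A`.
#' @examples
#' basic_reproduction_number(default_params(), "wildtype")
#' @export
basic_reproduction_number <- function(params,
                                      strain = c("wildtype", "mutant",
                                                 "w", "m"),
                                      S0 = params$shared$K) {
  stopifnot(inherits(params, "model_params"))
  strain <- match.arg(strain)
  strain <- if (strain %in% c("wildtype", "w")) "wildtype" else "mutant"
  s <- params$shared
  if (!is.finite(S0) || S0 < 0 || S0 > s$K)
    stop("'S0' must lie in [0, K]", call. = FALSE)
  alpha <- params[[strain]]$alpha
  phi <- params[[strain]]$phi
  grow <- s$r * (1 - S0 / s$K)
  horiz <- s$a * s$b * S0 * s$tau * s$B
  denom <- (s$a * S0 + s$delta) * (alpha + s$delta) * (s$tau + s$delta)
  A <- grow * (s$a * S0 + s$delta) * (s$tau + s$delta) +
    horiz * (alpha + (1 - phi) * s$delta)
  disc <- A^2 - 4 * grow * (1 - phi) * horiz * denom
  if (disc < 0) {
    if (disc < -1e-12 * max(A^2, 1))
      stop("negative discriminant in the reproduction-number formula; ",
           "check parameter values", call. = FALSE)
    disc <- 0
  }
  structure(list(strain = strain, R0 = (A + sqrt(disc)) / (2 * denom),
                 S0 = S0, A = A),
            class = "r0_result")
}

#' @export
print.r0_result <- function(x, ...) {
  cat(sprintf("R0[%s] = %.4f  (S0 = %.4g)\n", x$strain, x$R0, x$S0))
  invisible(x)
}

#' Selection gradient at the end of the epidemic
#'
#' Once (almost) every cell is infected there is no horizontal
#' transmission left, lysogens dominate the infected pool, and the mutant
#' declines in frequency on the logit scale at the constant rate
#' `S = -(alpha_m - alpha_w)`: the strain that reactivates more loses
#' lysogens faster.
#'
#' @param params a [model_params()] object.
#' @return An object of class `gradient_result`: list with `regime`
#'   (`"endemic"`), `gradient` (h^-1, logit scale) and `note`.
#' @export
endemic_selection_gradient <- function(params) {
  stopifnot(inherits(params, "model_params"))
  structure(list(
    regime = "endemic",
    gradient = -(params$mutant$alpha - params$wildtype$alpha),
    note = "exact in the high-prevalence regime; logit p, q and g share this slope"),
    class = "gradient_result")
}

#' @export
print.gradient_result <- function(x, ...) {
  cat(sprintf("selection gradient (%s regime): %.4g /h on the logit scale\n",
              x$regime, x$gradient))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' Differentiation of the mutant between two life stages
#'
#' The odds ratio `Q = odds(q) / odds(p)` comparing the mutant frequency
#' `q` among free virions with its frequency `p` among lysogens;
#' `log(Q) = logit(q) - logit(p)`, and `Q = 1` means no differentiation.
#'
#' @param q,p frequencies in `(0, 1)`.
#' @return An object of class `differentiation_result` with elements `Q`
#'   and `log_Q`.
#' @examples
#' differentiation(q = 0.8, p = 0.5)  # odds 4 vs 1 -> Q = 4
#' @export
differentiation <- function(q, p) {
  if (!is.finite(q) || !is.finite(p) || q <= 0 || q >= 1 || p <= 0 || p >= 1)
    stop("'q' and 'p' must lie strictly inside (0, 1); boundary ",
         "frequencies have infinite odds", call. = FALSE)
  lq <- qlogis(q) - qlogis(p)
  structure(list(Q = exp(lq), log_Q = lq), class = "differentiation_result")
}

#' Predicted equilibrium differentiation between virions and prophages
#'
#' At the end of the epidemic the differentiation of the mutant between
#' the free virus stage and lysogens converges to approximately
#' `alpha_m / alpha_w` (also valid just after introduction, before free
#' virions have completed a full infection cycle).
#'
#' @param params a [model_params()] object; requires `alpha_w > 0`.
#' @return A `differentiation_result` with the predicted `Q`.
#' @export
predicted_differentiation <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$wildtype$alpha <= 0)
    stop("predicted differentiation is undefined when alpha_w = 0",
         call. = FALSE)
  Q <- params$mutant$alpha / params$wildtype$alpha
  structure(list(Q = Q, log_Q = log(Q)), class = "differentiation_result")
}

#' @export
print.differentiation_result <- function(x, ...) {
  cat(sprintf("differentiation Q = %.4g (log Q = %.4g)\n", x$Q, x$log_Q))
  invisible(x)
}

# OLS slope of y on t (rows with NA dropped).
ols_slope <- function(t, y) {
  ok <- is.finite(t) & is.finite(y)
  if (sum(ok) < 2L) stop("need at least two finite points to fit a slope",
                         call. = FALSE)
  unname(coef(lm(y[ok] ~ t[ok]))[2L])
}

#' Onset selection gradient from a constant-S simulation
#'
#' At the start of an epidemic seeded at high susceptible density the
#' epidemic is driven by the lytic pathway and the mutant's logit
#' frequency among `Y` cells grows at a rate proportional to
#' `-(phi_m - phi_w)`. The proportionality constant depends on the
#' epidemic growth rate, so only the sign and the proportionality across
#' parameter sets are meaningful; this function returns the fitted
#' logit-`f` slope of a [simulate_constant_S()] run over `window`.
#'
#' Because only lysogens are introduced, `f` is undefined at time 0; the
#' window must therefore start at `t >= 1` h, after the system has
#' settled into its early exponential regime.
#'
#' @param params a [model_params()] object.
#' @param S0 pinned susceptible density (default `K`).
#' @param window time interval (h) over which the slope is fitted,
#'   default `c(1, 3)`.
#' @param P0,mutant_share initial conditions passed to [initial_state()].
#' @param dt simulation output step within the window (h).
#' @return A `gradient_result` with `regime = "onset"`.
#' @export
onset_gradient_check <- function(params, S0 = params$shared$K,
                                 window = c(1, 3), P0 = 0.01,
                                 mutant_share = 0.5, dt = 0.1) {
  stopifnot(inherits(params, "model_params"))
  if (length(window) != 2L || !all(is.finite(window)) ||
      window[2L] <= window[1L] || window[1L] < 1)
    stop("'window' must be an increasing interval starting at t >= 1 h",
         call. = FALSE)
  times <- c(0, seq(window[1L], window[2L], by = dt))
  tr <- simulate_constant_S(params, initial_state(P0, mutant_share, params),
                            S0 = S0, times = times)
  inw <- tr$time >= window[1L]
  slope <- ols_slope(tr$time[inw], logit(tr$f[inw]))
  structure(list(
    regime = "onset", gradient = slope,
    note = paste0("logit-f slope over [", window[1L], ", ", window[2L],
                  "] h with S pinned at ", format(S0, digits = 4),
                  "; proportional to -(phi_m - phi_w)")),
    class = "gradient_result")
}

#' Fitted logit slope over the tail of a trajectory or series
#'
#' Convenience used by the endemic-theory checks: fits an OLS slope of a
#' logit response against time over the final `fraction` of the time
#' span (default the last third).
#'
#' @param time,value numeric vectors; `value` is on the logit scale.
#' @param fraction fraction of the time span, from the end, to use.
#' @return The fitted slope (per hour).
#' @export
tail_slope <- function(time, value, fraction = 1 / 3) {
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop("'fraction' must lie in (0, 1]", call. = FALSE)
  t0 <- max(time) - fraction * (max(time) - min(time))
  keep <- time >= t0
  ols_slope(time[keep], value[keep])
}
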