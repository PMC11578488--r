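#' State vector of the chemostat system
#'
#' The seven compartment densities: susceptible cells `S`, lysogens `L_w`,
#' `L_m` (carrying the wildtype / mutant prophage), cells committed to
#' lysis `Y_w`, `Y_m` (phages replicating in the cytoplasm), and free
#' virions `V_w`, `V_m`. Densities are in cells (or virions) per chemostat,
#' on the same scale as the carrying capacity `K`.
#'
#' @param S,L_w,L_m,Y_w,Y_m,V_w,V_m non-negative densities.
#' @return Named numeric vector of class `state_vector`.
#' @export
state_vector <- function(S, L_w = 0, L_m = 0, Y_w = 0, Y_m = 0,
                         V_w = 0, V_m = 0) {
  y <- c(S = S, L_w = L_w, L_m = L_m, Y_w = Y_w, Y_m = Y_m,
         V_w = V_w, V_m = V_m)
  if (!all(is.finite(y)) || any(y < 0))
    stop("state densities must be finite and non-negative", call. = FALSE)
  structure(y, class = "state_vector")
}

state_names <- c("S", "L_w", "L_m", "Y_w", "Y_m", "V_w", "V_m")

#' Mean life-history traits of the viral population
#'
#' The mean probability of lysogenization is taken across the free virus
#' stage (weights `q`, the mutant frequency among virions, since it is
#' virions that infect) and the mean reactivation rate across prophages
#' (weights `p`, the mutant frequency among lysogens):
#' `phi_bar = q * phi_m + (1 - q) * phi_w`,
#' `alpha_bar = p * alpha_m + (1 - p) * alpha_w`.
#'
#' @param q mutant frequency among free virions, in `[0, 1]`.
#' @param p mutant frequency among lysogens, in `[0, 1]`.
#' @param params a [model_params()] object.
#' @return Named vector `c(phi_bar, alpha_bar)`.
#' @export
mean_traits <- function(q, p, params) {
  stopifnot(inherits(params, "model_params"))
  if (!is.finite(q) || q < 0 || q > 1 || !is.finite(p) || p < 0 || p > 1)
    stop("'q' and 'p' must be frequencies in [0, 1]", call. = FALSE)
  c(phi_bar = q * params$mutant$phi + (1 - q) * params$wildtype$phi,
    alpha_bar = p * params$mutant$alpha + (1 - p) * params$wildtype$alpha)
}

#' Time derivatives of the strain-resolved model
#'
#' Reference (pure R) implementation of the right-hand side of the
#' delayed-lysis model. Susceptibles and lysogens grow logistically at
#' per-capita rate \code{r (1 - N/K)}; virions adsorb at rate `a` and inject
#' their genome with probability `b`, so each strain exerts a force of
#' infection `a b V_k S`; an infection lysogenizes with probability
#' `phi_k`, otherwise the cell joins `Y_k`; prophages reactivate at rate
#' `alpha_k`; `Y` cells lyse at rate `tau`, releasing `B` virions; every
#' compartment is washed out at the dilution rate `delta`. Summing the
#' strain-resolved equations recovers the aggregate system in which the
#' lysogenization and reactivation rates are the population means of
#' [mean_traits()].
#'
#' @param state a [state_vector()] (or named non-negative vector).
#' @param params a [model_params()] object.
#' @return Named numeric vector of time derivatives (same order as the
#'   state).
#' @export
derivatives <- function(state, params) {
  stopifnot(inherits(params, "model_params"))
  y <- unclass(state)[state_names]
  if (any(is.na(y)) || !all(is.finite(y)))
    stop("state must contain finite values for ",
         paste(state_names, collapse = ", "), call. = FALSE)
  if (any(y < 0))
    stop("state densities must be non-negative", call. = FALSE)
  p <- params_vector(params)
  if (!all(is.finite(p)))
    stop("model parameters must be finite", call. = FALSE)
  S <- y[["S"]]
  N <- sum(y[c("S", "L_w", "L_m", "Y_w", "Y_m")])
  growth <- p[["r"]] * (1 - N / p[["K"]])
  foi_w <- p[["a"]] * p[["b"]] * y[["V_w"]] * S
  foi_m <- p[["a"]] * p[["b"]] * y[["V_m"]] * S
  d <- p[["delta"]]
  c(S   = growth * S - (foi_w + foi_m) - d * S,
    L_w = growth * y[["L_w"]] + p[["phi_w"]] * foi_w -
      (p[["alpha_w"]] + d) * y[["L_w"]],
    L_m = growth * y[["L_m"]] + p[["phi_m"]] * foi_m -
      (p[["alpha_m"]] + d) * y[["L_m"]],
    Y_w = (1 - p[["phi_w"]]) * foi_w + p[["alpha_w"]] * y[["L_w"]] -
      (p[["tau"]] + d) * y[["Y_w"]],
    Y_m = (1 - p[["phi_m"]]) * foi_m + p[["alpha_m"]] * y[["L_m"]] -
      (p[["tau"]] + d) * y[["Y_m"]],
    V_w = p[["tau"]] * y[["Y_w"]] * p[["B"]] - p[["a"]] * N * y[["V_w"]] -
      d * y[["V_w"]],
    V_m = p[["tau"]] * y[["Y_m"]] * p[["B"]] - p[["a"]] * N * y[["V_m"]] -
      d * y[["V_m"]])
}

#' Initial state of a chemostat experiment
#'
#' Bacteria start at carrying capacity `K` with prevalence `P0`; all
#' infected cells are lysogens (only prophages are introduced), split
#' between the mutant and the wildtype according to `mutant_share`. No `Y`
#' cells and no free virions are present at time 0.
#'
#' @param P0 initial prevalence, in `[0, 1]`.
#' @param mutant_share initial mutant share among lysogens, in `[0, 1]`.
#' @param params a [model_params()] object (supplies `K`).
#' @return A [state_vector()].
#' @examples
#' initial_state(0.01, 0.5, default_params())  # epidemic treatment
#' @export
initial_state <- function(P0, mutant_share, params) {
  stopifnot(inherits(params, "model_params"))
  if (!is.finite(P0) || P0 < 0 || P0 > 1)
    stop("'P0' must be a prevalence in [0, 1]", call. = FALSE)
  if (!is.finite(mutant_share) || mutant_share < 0 || mutant_share > 1)
    stop("'mutant_share' must be a frequency in [0, 1]", call. = FALSE)
  K <- params$shared$K
  state_vector(S = (1 - P0) * K,
               L_w = (1 - mutant_share) * P0 * K,
               L_m = mutant_share * P0 * K)
}

# Observables from a matrix of states (columns named as state_names or the
# 5-state subset). Frequencies with empty denominators are NaN. Small
# solver undershoots are clamped to zero before forming ratios.
compute_observables <- function(states, instantaneous = FALSE) {
  cl <- pmax(states, 0)
  if (instantaneous) {
    N <- cl[, "S"] + cl[, "L_w"] + cl[, "L_m"]
    L <- cl[, "L_w"] + cl[, "L_m"]
    V <- cl[, "V_w"] + cl[, "V_m"]
    P <- ifelse(N > 0, 1 - cl[, "S"] / N, NaN)
    p <- ifelse(L > 0, cl[, "L_m"] / L, NaN)
    q <- ifelse(V > 0, cl[, "V_m"] / V, NaN)
    f <- rep(NaN, nrow(cl))
    g <- p
  } else {
    N <- cl[, "S"] + cl[, "L_w"] + cl[, "L_m"] + cl[, "Y_w"] + cl[, "Y_m"]
    L <- cl[, "L_w"] + cl[, "L_m"]
    Y <- cl[, "Y_w"] + cl[, "Y_m"]
    V <- cl[, "V_w"] + cl[, "V_m"]
    P <- ifelse(N > 0, 1 - cl[, "S"] / N, NaN)
    p <- ifelse(L > 0, cl[, "L_m"] / L, NaN)
    q <- ifelse(V > 0, cl[, "V_m"] / V, NaN)
    f <- ifelse(Y > 0, cl[, "Y_m"] / Y, NaN)
    g <- ifelse(Y + L > 0, (cl[, "Y_m"] + cl[, "L_m"]) / (Y + L), NaN)
  }
  data.frame(P = P, p = p, q = q, f = f, g = g)
}

# Shared integration path. `model` selects the compiled rhs; `const_S`
# pins dS/dt to zero (onset approximation). State is integrated in units
# of K; relative tolerance 1e-8 and absolute tolerance 1e-6 on the scaled
# densities. Undershoots below -1e-9 (in units of K) abort.
integrate_model <- function(params, init, times, model = c("delay", "instant"),
                            const_S = FALSE, use_compiled = TRUE,
                            rtol = 1e-8, atol = 1e-6) {
  model <- match.arg(model)
  stopifnot(inherits(params, "model_params"))
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("'times' must be an increasing vector of at least two times",
         call. = FALSE)
  p <- params_vector(params)
  K <- p[["K"]]
  nm <- if (model == "delay") state_names else
    c("S", "L_w", "L_m", "V_w", "V_m")
  y0 <- unclass(init)
  if (model == "instant" && length(y0) == 7L) {
    if (any(y0[c("Y_w", "Y_m")] != 0))
      stop("the instantaneous-lysis model has no Y compartment; ",
           "supply an initial state with Y_w = Y_m = 0", call. = FALSE)
    y0 <- y0[nm]
  }
  y0 <- y0[nm]
  if (any(is.na(y0)) || any(y0 < 0) || !all(is.finite(y0)))
    stop("initial state must be finite, non-negative and named ",
         paste(nm, collapse = ", "), call. = FALSE)
  cparms <- c(p[["alpha_w"]], p[["alpha_m"]], p[["phi_w"]], p[["phi_m"]],
              p[["a"]] * K, p[["b"]], p[["tau"]], p[["B"]], p[["r"]],
              p[["delta"]], as.numeric(const_S))
  yscaled <- y0 / K
  if (use_compiled) {
    out <- deSolve::ode(
      y = yscaled, times = times,
      func = if (model == "delay") "derivs_delay" else "derivs_instant",
      parms = cparms, dllname = "phagevo", initfunc = "initmod_phage",
      method = "lsoda", rtol = rtol, atol = atol)
  } else {
    rhs <- function(t, y, pp) {
      S <- y[1L]
      growth <- pp[9L] * (1 - sum(y[seq_len(length(y) - 2L)]))
      if (model == "delay") {
        foi_w <- pp[5L] * pp[6L] * y[6L] * S
        foi_m <- pp[5L] * pp[6L] * y[7L] * S
        N <- sum(y[1:5])
        dy <- c(
          if (const_S) 0 else growth * S - (foi_w + foi_m) - pp[10L] * S,
          growth * y[2L] + pp[3L] * foi_w - (pp[1L] + pp[10L]) * y[2L],
          growth * y[3L] + pp[4L] * foi_m - (pp[2L] + pp[10L]) * y[3L],
          (1 - pp[3L]) * foi_w + pp[1L] * y[2L] - (pp[7L] + pp[10L]) * y[4L],
          (1 - pp[4L]) * foi_m + pp[2L] * y[3L] - (pp[7L] + pp[10L]) * y[5L],
          pp[7L] * y[4L] * pp[8L] - pp[5L] * N * y[6L] - pp[10L] * y[6L],
          pp[7L] * y[5L] * pp[8L] - pp[5L] * N * y[7L] - pp[10L] * y[7L])
      } else {
        foi_w <- pp[5L] * pp[6L] * y[4L] * S
        foi_m <- pp[5L] * pp[6L] * y[5L] * S
        N <- sum(y[1:3])
        dy <- c(
          if (const_S) 0 else growth * S - (foi_w + foi_m) - pp[10L] * S,
          growth * y[2L] + pp[3L] * foi_w - (pp[1L] + pp[10L]) * y[2L],
          growth * y[3L] + pp[4L] * foi_m - (pp[2L] + pp[10L]) * y[3L],
          pp[8L] * ((1 - pp[3L]) * foi_w + pp[1L] * y[2L]) -
            pp[5L] * N * y[4L] - pp[10L] * y[4L],
          pp[8L] * ((1 - pp[4L]) * foi_m + pp[2L] * y[3L]) -
            pp[5L] * N * y[5L] - pp[10L] * y[5L])
      }
      list(dy)
    }
    out <- deSolve::ode(y = yscaled, times = times, func = rhs,
                        parms = cparms, method = "lsoda",
                        rtol = rtol, atol = atol)
  }
  if (nrow(out) < length(times) || any(!is.finite(out[, -1L])))
    stop(sprintf(
      "ODE integration failed near t = %.3g h", out[nrow(out), 1L]),
      call. = FALSE)
  states <- out[, -1L, drop = FALSE]
  if (min(states) < -1e-9)
    stop(sprintf(
      "integration produced a negative density (%.3g K) at t = %.3g h",
      min(states), out[which(states < -1e-9, arr.ind = TRUE)[1L, 1L], 1L]),
      call. = FALSE)
  colnames(states) <- nm
  states * K
}

# Assemble a trajectory data.frame (time, states, observables).
as_trajectory <- function(times, states, params, model) {
  obs <- compute_observables(states, instantaneous = model == "instant")
  tr <- cbind(data.frame(time = times), as.data.frame(states), obs)
  attr(tr, "params") <- params
  attr(tr, "model") <- model
  class(tr) <- c("phage_trajectory", "data.frame")
  tr
}

#' Simulate the delayed-lysis model
#'
#' Integrates the strain-resolved seven-compartment system with a
#' stiff-capable solver (`lsoda`) and derives the observables at every
#' requested time: prevalence `P = 1 - S/N`, the mutant frequencies `p`
#' (among lysogens), `q` (among virions), `f` (among `Y` cells) and `g`
#' (among all infected cells, the `Y`/`L`-weighted mean of `f` and `p`).
#' Frequencies whose denominator is empty (e.g. `f` at time 0 when only
#' lysogens are present) are reported as `NaN`.
#'
#' @param params a [model_params()] object.
#' @param init a [state_vector()]; see [initial_state()].
#' @param times increasing vector of times (h); the first element is the
#'   time of `init`.
#' @param use_compiled integrate with the compiled right-hand side
#'   (default) or the pure-R reference implementation.
#' @param rtol,atol solver tolerances, applied to densities rescaled by
#'   the carrying capacity.
#' @return A `phage_trajectory` data frame with columns `time`, the seven
#'   densities, and `P`, `p`, `q`, `f`, `g`.
#' @examples
#' tr <- simulate_model(default_params(),
#'                      initial_state(0.01, 0.5, default_params()),
#'                      times = 0:60)
#' tail(tr[, c("time", "P", "g", "q")])
#' @export
simulate_model <- function(params, init, times, use_compiled = TRUE,
                           rtol = 1e-8, atol = 1e-6) {
  states <- integrate_model(params, init, times, model = "delay",
                            use_compiled = use_compiled,
                            rtol = rtol, atol = atol)
  as_trajectory(times, states, params, "delay")
}

#' Simulate with the susceptible density pinned (epidemic onset regime)
#'
#' Identical to [simulate_model()] except that the susceptible density is
#' held constant at `S0` (its derivative is forced to zero). This is the
#' regime in which the onset selection gradient of the virulent strain is
#' proportional to `-(phi_m - phi_w)`; the simulation serves as the
#' numerical oracle for that approximation.
#'
#' @inheritParams simulate_model
#' @param S0 the constant susceptible density; replaces `init["S"]`.
#' @return A `phage_trajectory` data frame.
#' @export
simulate_constant_S <- function(params, init, S0, times, use_compiled = TRUE,
                                rtol = 1e-8, atol = 1e-6) {
  if (!is.finite(S0) || S0 < 0)
    stop("'S0' must be a non-negative density", call. = FALSE)
  y0 <- unclass(init)
  y0[["S"]] <- S0
  states <- integrate_model(params, y0, times, model = "delay",
                            const_S = TRUE, use_compiled = use_compiled,
                            rtol = rtol, atol = atol)
  as_trajectory(times, states, params, "delay")
}

#' Simulate the instantaneous-lysis nested model
#'
#' The nested five-compartment variant in which lysis is instantaneous:
#' there is no `Y` stage, and lytic infections and prophage reactivations
#' release `B` virions immediately. The frequency of infected cells `g`
#' reduces to `p` and `f` is undefined. This is the model against which
#' the delayed-lysis model is compared by AIC.
#'
#' @inheritParams simulate_model
#' @param init a [state_vector()] (its `Y` components must be zero) or a
#'   named 5-vector `(S, L_w, L_m, V_w, V_m)`.
#' @return A `phage_trajectory` data frame with the five densities and
#'   observables `P`, `p`, `q` (`f` is `NaN`, `g = p`).
#' @export
simulate_original_model <- function(params, init, times, use_compiled = TRUE,
                                    rtol = 1e-8, atol = 1e-6) {
  states <- integrate_model(params, init, times, model = "instant",
                            use_compiled = use_compiled,
                            rtol = rtol, atol = atol)
  as_trajectory(times, states, params, "instant")
}

#' Export a trajectory as tidy CSV
#'
#' @param trajectory a `phage_trajectory` data frame.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "phage_trajectory"))
  write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
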