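#' Parameter bounds for the likelihood optimization
#'
#' Box bounds for the free parameters, enforced during optimization by
#' smooth reparameterisations: probabilities (and prevalences) are mapped
#' through a log-odds transform rescaled to their bounds, positive rates
#' through a log transform rescaled to theirs. The default box is
#' `phi_w, phi_m` in `[1e-4, 0.999]`; `a` in `[1e-10, 1e-6]`; `b` in
#' `[1e-4, 0.2]`; `tau` in `[0.1, 10]`; `r` in `[0.81, 5]` (the growth
#' rate must exceed the dilution rate 0.8 for the culture to persist);
#' initial prevalences in `[1e-3, 0.999]` and the initial mutant share
#' `p0` in `[0.01, 0.99]`. Every entry can be overridden.
#'
#' @param treatments character vector of treatment labels (one initial
#'   prevalence `P0_<treatment>` is estimated per treatment).
#' @param overrides named list of `c(lo, hi)` pairs.
#' @return A data frame with columns `param`, `lo`, `hi`, `scale`.
#' @export
default_bounds <- function(treatments = c("epidemic", "endemic"),
                           overrides = list()) {
  b <- data.frame(
    param = c("phi_w", "phi_m", "a", "b", "r", "tau",
              paste0("P0_", treatments), "p0"),
    lo = c(1e-4, 1e-4, 1e-10, 1e-4, 0.81, 0.1,
           rep(1e-3, length(treatments)), 0.01),
    hi = c(0.999, 0.999, 1e-6, 0.2, 5, 10,
           rep(0.999, length(treatments)), 0.99),
    scale = c("prob", "prob", "log", "prob", "log", "log",
              rep("prob", length(treatments)), "prob"),
    stringsAsFactors = FALSE)
  for (nm in names(overrides)) {
    i <- match(nm, b$param)
    if (is.na(i)) stop("unknown bound override: ", nm, call. = FALSE)
    b$lo[i] <- overrides[[nm]][1L]
    b$hi[i] <- overrides[[nm]][2L]
  }
  if (any(b$lo >= b$hi) || any(b$lo <= 0 & b$scale == "log"))
    stop("invalid bounds: need lo < hi (and lo > 0 on the log scale)",
         call. = FALSE)
  b
}

# Bounded <-> unconstrained transforms (vectorised over one parameter).
to_unconstrained <- function(x, lo, hi, scale) {
  u <- if (scale == "log") (log(x) - log(lo)) / (log(hi) - log(lo))
       else (x - lo) / (hi - lo)
  qlogis(pmin(pmax(u, 1e-10), 1 - 1e-10))
}
from_unconstrained <- function(z, lo, hi, scale) {
  u <- plogis(unname(z))
  if (scale == "log") exp(log(lo) + u * (log(hi) - log(lo)))
  else lo + u * (hi - lo)
}

theta_parameter_names <- function(treatments, model = "delay") {
  nm <- c("phi_w", "phi_m", "a", "b", "r",
          if (model == "delay") "tau",
          paste0("P0_", treatments), "p0")
  nm
}

check_fixed <- function(fixed) {
  need <- c("K", "delta", "B", "alpha_w", "alpha_m")
  miss <- setdiff(need, names(fixed))
  if (length(miss))
    stop("'fixed' must supply ", paste(miss, collapse = ", "),
         call. = FALSE)
  fixed
}

theta_to_params <- function(theta, fixed, model = "delay") {
  default_params(alpha_w = fixed$alpha_w, alpha_m = fixed$alpha_m,
                 phi_w = theta[["phi_w"]], phi_m = theta[["phi_m"]],
                 a = theta[["a"]], b = theta[["b"]], r = theta[["r"]],
                 tau = if (model == "delay") theta[["tau"]] else 1,
                 B = fixed$B, K = fixed$K, delta = fixed$delta)
}

#' Step 1: direct estimation of the prophage reactivation rates
#'
#' In the high-prevalence regime the mutant's logit frequency among
#' infected cells declines at rate `S = -(alpha_m - alpha_w)` while its
#' differentiation between virions and infected cells settles at
#' `Q = alpha_m / alpha_w`. Inverting these two relations gives
#' `alpha_w = S / (1 - Q)` and `alpha_m = S Q / (1 - Q)`.
#'
#' Per chemostat, only observations from the first time the observed
#' prevalence reaches `prevalence_threshold` are retained (first crossing
#' of the noisy series, no smoothing). `S` is the slope of a linear model
#' of `logit g` on time — by default a single model with chemostat-specific
#' intercepts and a common slope; `method = "per_chemostat"` instead fits
#' one slope per chemostat and averages. `Q` is the geometric mean of the
#' observed odds ratio, computed as `exp(mean(logit q - logit g))` over
#' all retained points (the frequency among lysogens is substituted by
#' the measured `g`, which converges to it at high prevalence).
#'
#' @param dataset a `phage_dataset`.
#' @param prevalence_threshold prevalence a chemostat must reach before
#'   its data enter the estimation (default 0.95).
#' @param method `"joint"` (common slope, default) or `"per_chemostat"`.
#' @return An object of class `alpha_estimate`: list with `S_hat`,
#'   `Q_hat`, `alpha_w`, `alpha_m`, `n_points`, `threshold_times` (first
#'   crossing per retained chemostat) and `valid` (`FALSE` when the
#'   inverted rates are negative or `Q_hat` is 1, e.g. when `g` and `q`
#'   coincide).
#' @export
estimate_alphas <- function(dataset, prevalence_threshold = 0.95,
                            method = c("joint", "per_chemostat")) {
  method <- match.arg(method)
  validate_dataset(dataset)
  if (!is.finite(prevalence_threshold) ||
      prevalence_threshold <= 0 || prevalence_threshold >= 1)
    stop("'prevalence_threshold' must lie in (0, 1)", call. = FALSE)
  thr <- qlogis(prevalence_threshold)
  keep <- list()
  crossing <- c()
  for (key in unique(paste(dataset$treatment, dataset$chemostat,
                           sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    d <- dataset[dataset$treatment == parts[1L] &
                   dataset$chemostat == parts[2L], ]
    d <- d[order(d$time_h), ]
    hit <- which(!is.na(d$logit_P) & d$logit_P >= thr)
    if (!length(hit)) next
    t0 <- d$time_h[hit[1L]]
    d <- d[d$time_h >= t0, ]
    d$series <- paste(parts[1L], parts[2L], sep = ":")
    keep[[key]] <- d
    crossing[d$series[1L]] <- t0
  }
  if (!length(keep))
    stop("no chemostat reaches the prevalence threshold ",
         prevalence_threshold, "; cannot estimate reactivation rates",
         call. = FALSE)
  d <- do.call(rbind, keep)
  d <- d[!is.na(d$logit_g), ]
  if (length(unique(d$time_h)) < 2L)
    stop("insufficient post-threshold data to fit a slope", call. = FALSE)
  if (method == "joint") {
    S_hat <- unname(coef(lm(logit_g ~ 0 + series + time_h,
                            data = d))[["time_h"]])
  } else {
    slopes <- vapply(split(d, d$series), function(s) {
      if (length(unique(s$time_h)) < 2L) return(NA_real_)
      ols_slope(s$time_h, s$logit_g)
    }, numeric(1))
    S_hat <- mean(slopes, na.rm = TRUE)
  }
  lq <- d$logit_q - d$logit_g
  lq <- lq[is.finite(lq)]
  Q_hat <- exp(mean(lq))
  if (abs(Q_hat - 1) < .Machine$double.eps^0.5) {
    alpha_w <- alpha_m <- NA_real_
    valid <- FALSE
  } else {
    alpha_w <- S_hat / (1 - Q_hat)
    alpha_m <- S_hat * Q_hat / (1 - Q_hat)
    valid <- is.finite(alpha_w) && is.finite(alpha_m) &&
      alpha_w >= 0 && alpha_m >= 0
  }
  structure(list(S_hat = S_hat, Q_hat = Q_hat,
                 alpha_w = alpha_w, alpha_m = alpha_m,
                 n_points = nrow(d), threshold_times = crossing,
                 method = method, valid = valid),
            class = "alpha_estimate")
}

#' @export
print.alpha_estimate <- function(x, ...) {
  cat("Reactivation-rate estimates (step 1)\n")
  cat(sprintf("  slope S = %.4g /h, differentiation Q = %.4g (%d points)\n",
              x$S_hat, x$Q_hat, x$n_points))
  cat(sprintf("  alpha_w = %.4g /h, alpha_m = %.4g /h%s\n",
              x$alpha_w, x$alpha_m,
              if (x$valid) "" else "  [INVALID]"))
  invisible(x)
}

# Precomputed observation layout: per treatment, the unique time grid,
# each row's index into that grid, and the observed logit matrix. Built
# once per optimization so likelihood evaluations avoid any joins.
prepare_layout <- function(dataset) {
  lapply(split(dataset, dataset$treatment), function(d) {
    tgrid <- sort(unique(d$time_h))
    list(tgrid = tgrid, idx = match(d$time_h, tgrid),
         obs = cbind(P = d$logit_P, g = d$logit_g, q = d$logit_q))
  })
}

# Compiled-model parameter vector straight from theta + fixed, skipping
# the validating constructors (hot path; validity is enforced by the
# bound transforms upstream).
theta_cparms <- function(theta, fixed, model = "delay") {
  c(fixed$alpha_w, fixed$alpha_m, theta[["phi_w"]], theta[["phi_m"]],
    theta[["a"]] * fixed$K, theta[["b"]],
    if (model == "delay") theta[["tau"]] else 1,
    fixed$B, theta[["r"]], fixed$delta, 0)
}

# Deterministic logit responses on a time grid (lean hot-path version of
# deterministic_logits; returns an n x 3 matrix, non-finite -> NA).
# Bypasses the user-facing wrappers: one deSolve call, minimal checks.
predicted_logits <- function(params, P0, p0, tgrid, model = "delay") {
  pv <- params_vector(params)
  K <- pv[["K"]]
  cparms <- c(pv[["alpha_w"]], pv[["alpha_m"]], pv[["phi_w"]], pv[["phi_m"]],
              pv[["a"]] * K, pv[["b"]], pv[["tau"]], pv[["B"]], pv[["r"]],
              pv[["delta"]], 0)
  predicted_logits_raw(cparms, P0, p0, tgrid, model)
}

predicted_logits_raw <- function(cparms, P0, p0, tgrid, model = "delay") {
  y0 <- if (model == "delay")
    c(S = 1 - P0, L_w = (1 - p0) * P0, L_m = p0 * P0,
      Y_w = 0, Y_m = 0, V_w = 0, V_m = 0)
  else
    c(S = 1 - P0, L_w = (1 - p0) * P0, L_m = p0 * P0, V_w = 0, V_m = 0)
  # solver chatter is suppressed: failed integrations are detected below
  # and surface as a penalized (infinite) likelihood
  out <- suppressWarnings(deSolve::lsoda(
    y = y0, times = c(0, tgrid),
    func = if (model == "delay") "derivs_delay" else "derivs_instant",
    parms = cparms, dllname = "phagevo", initfunc = "initmod_phage",
    rtol = 1e-8, atol = 1e-6))
  states <- out[, -1L, drop = FALSE]
  if (nrow(out) < length(tgrid) + 1L || any(!is.finite(states)) ||
      min(states) < -1e-9)
    stop("ODE integration failed", call. = FALSE)
  cl <- pmax(states[-1L, , drop = FALSE], 0)  # units of K; ratios cancel
  eps <- 1e-12
  if (model == "delay") {
    L <- cl[, "L_w"] + cl[, "L_m"]
    Y <- cl[, "Y_w"] + cl[, "Y_m"]
    N <- cl[, "S"] + L + Y
    V <- cl[, "V_w"] + cl[, "V_m"]
    P <- 1 - cl[, "S"] / N
    g <- (cl[, "L_m"] + cl[, "Y_m"]) / (L + Y)
    q <- cl[, "V_m"] / V
  } else {
    L <- cl[, "L_w"] + cl[, "L_m"]
    N <- cl[, "S"] + L
    V <- cl[, "V_w"] + cl[, "V_m"]
    P <- 1 - cl[, "S"] / N
    g <- cl[, "L_m"] / L
    q <- cl[, "V_m"] / V
  }
  m <- cbind(P = P, g = g, q = q)
  m <- qlogis(pmin(pmax(m, eps), 1 - eps))
  m[!is.finite(m)] <- NA_real_
  m
}

# Residuals of a dataset (given as a prepared layout) around the
# deterministic trajectories implied by theta. Returns list of numeric
# vectors P, g, q (NAs dropped).
layout_residuals <- function(theta, layout, fixed, model = "delay") {
  cparms <- theta_cparms(theta, fixed, model)
  res <- list(P = numeric(0), g = numeric(0), q = numeric(0))
  for (trt in names(layout)) {
    lay <- layout[[trt]]
    pred <- predicted_logits_raw(cparms, theta[[paste0("P0_", trt)]],
                                 theta[["p0"]], lay$tgrid, model)
    for (r in c("P", "g", "q")) {
      e <- lay$obs[, r] - pred[lay$idx, r]
      res[[r]] <- c(res[[r]], e[!is.na(e)])
    }
  }
  res
}

#' Gaussian negative log-likelihood of the logit-scale observations
#'
#' Simulates each treatment once from its initial conditions (taken from
#' `theta`) and scores the observed logit prevalence and logit mutant
#' frequencies against the simulated trajectories under i.i.d. Gaussian
#' measurement error, summed over treatments, chemostats, times and the
#' three responses. Missing observations are skipped. When `sigmas` is
#' `NULL` the three error SDs are profiled analytically (the Gaussian
#' variance MLE given the residuals), which at the optimum is equivalent
#' to estimating them jointly; the profiled SD is floored at 1e-3, an
#' order of magnitude below the smallest measurement SD considered in
#' the simulation study and at the accuracy limit of the ODE solution on
#' the logit scale (the logit amplifies solver error without bound as
#' the prevalence saturates), so that a numerically perfect fit keeps
#' the likelihood finite and residuals below solver precision are not
#' spuriously distinguished.
#'
#' @param theta named list/vector of free parameters: `phi_w`, `phi_m`,
#'   `a`, `b`, `r`, `tau` (delayed-lysis model only), one `P0_<treatment>`
#'   per treatment, and `p0`.
#' @param dataset a `phage_dataset`.
#' @param fixed named list with `K`, `delta`, `B`, `alpha_w`, `alpha_m`.
#' @param sigmas optional named vector `c(P=, g=, q=)` of error SDs; if
#'   `NULL` they are profiled.
#' @param model `"delay"` (with the `Y` stage) or `"instant"`.
#' @return The negative log-likelihood (scalar). Attributes: `parts`
#'   (per-response contributions) and `sigmas` (profiled or supplied).
#'   Returns `Inf` if the ODE integration fails at this `theta`.
#' @export
negative_log_likelihood <- function(theta, dataset, fixed, sigmas = NULL,
                                    model = c("delay", "instant")) {
  model <- match.arg(model)
  layout <- if (is.list(dataset) && !is.data.frame(dataset) &&
                  all(vapply(dataset, function(x) is.list(x) &&
                               all(c("tgrid", "idx", "obs") %in% names(x)),
                             logical(1))))
    dataset else prepare_layout(validate_dataset(dataset))
  fixed <- check_fixed(fixed)
  theta <- as.list(theta)
  res <- tryCatch(layout_residuals(theta, layout, fixed, model),
                  error = function(e) NULL)
  if (is.null(res)) return(Inf)
  parts <- setNames(numeric(3), c("P", "g", "q"))
  sig_out <- setNames(numeric(3), c("P", "g", "q"))
  for (r in c("P", "g", "q")) {
    e <- res[[r]]
    n <- length(e)
    if (n == 0L) { parts[r] <- 0; sig_out[r] <- NA_real_; next }
    if (is.null(sigmas)) {
      s2 <- max(mean(e^2), 1e-6)
      parts[r] <- n / 2 * (log(2 * pi) + log(s2) + 1)
      sig_out[r] <- sqrt(s2)
    } else {
      s <- sigmas[[r]]
      parts[r] <- -sum(dnorm(e, mean = 0, sd = s, log = TRUE))
      sig_out[r] <- s
    }
  }
  structure(sum(parts), parts = parts, sigmas = sig_out)
}

# Build the objective over the unconstrained coordinates of `free` params,
# with the remaining theta entries pinned at `pinned`.
make_objective <- function(dataset, fixed, bounds, free, pinned,
                           model = "delay") {
  layout <- prepare_layout(dataset)
  bsub <- bounds[match(free, bounds$param), ]
  function(z) {
    theta <- pinned
    for (i in seq_along(free))
      theta[[free[i]]] <- from_unconstrained(z[i], bsub$lo[i], bsub$hi[i],
                                             bsub$scale[i])
    res <- tryCatch(layout_residuals(theta, layout, fixed, model),
                    error = function(e) NULL)
    if (is.null(res)) return(Inf)
    nll <- 0
    for (r in c("P", "g", "q")) {
      n <- length(res[[r]])
      if (n == 0L) next
      nll <- nll + n / 2 * (log(2 * pi) +
                              log(max(mean(res[[r]]^2), 1e-6)) + 1)
    }
    nll
  }
}

theta_to_z <- function(theta, bounds, free) {
  vapply(free, function(nm) {
    i <- match(nm, bounds$param)
    to_unconstrained(theta[[nm]], bounds$lo[i], bounds$hi[i],
                     bounds$scale[i])
  }, numeric(1))
}
z_to_theta <- function(z, bounds, free, pinned = list()) {
  theta <- pinned
  for (i in seq_along(free)) {
    j <- match(free[i], bounds$param)
    theta[[free[i]]] <- from_unconstrained(z[i], bounds$lo[j], bounds$hi[j],
                                           bounds$scale[j])
  }
  theta
}

# Nelder-Mead with simplex restarts inside a shared evaluation budget.
# A stalled simplex (maxit hit, or converged but still improving) is
# re-initialised at its own endpoint, which restores search-direction
# diversity. The run counts as converged when a restart terminates by
# optim's own criterion while improving the negative log-likelihood by
# less than `improve_tol` (absolute units; the default 0.01 is two
# orders of magnitude below the AIC-relevant scale of 2).
optim_restarts <- function(z0, obj, control = list()) {
  maxeval <- if (is.null(control$maxit)) 5000 else control$maxit
  reltol <- if (is.null(control$reltol)) 1e-8 else control$reltol
  improve_tol <- if (is.null(control$improve_tol)) 1e-2
                 else control$improve_tol
  used <- 0
  z <- z0
  value <- Inf
  converged <- FALSE
  for (seg in 1:40) {
    budget <- maxeval - used
    if (budget < 50) break
    ans <- tryCatch(
      optim(z, obj, method = "Nelder-Mead",
            control = list(maxit = budget, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(ans)) break
    used <- used + ans$counts[[1L]]
    if (!is.finite(ans$value)) break
    improved <- !is.finite(value) || ans$value < value - improve_tol
    z <- ans$par
    value <- min(value, ans$value)
    if (ans$convergence == 0L && !improved) {
      converged <- TRUE
      break
    }
  }
  list(par = z, value = value,
       convergence = if (converged) 0L else 1L, counts = used)
}

# Uniform start draws: uniform on each parameter's natural scale between
# its bounds (geometrically for log-scale parameters).
draw_starts <- function(n, bounds, free) {
  m <- matrix(NA_real_, nrow = n, ncol = length(free),
              dimnames = list(NULL, free))
  for (i in seq_along(free)) {
    j <- match(free[i], bounds$param)
    u <- runif(n)
    m[, i] <- if (bounds$scale[j] == "log")
      exp(log(bounds$lo[j]) + u * (log(bounds$hi[j]) - log(bounds$lo[j])))
    else bounds$lo[j] + u * (bounds$hi[j] - bounds$lo[j])
  }
  m
}

#' Step 2: multi-start Nelder-Mead maximum-likelihood fit
#'
#' Minimises [negative_log_likelihood()] over the free parameters with the
#' reactivation rates (and `K`, `delta`, `B`) held fixed. The landscape
#' has local optima, so the optimization is restarted from `n_starts`
#' uniformly drawn points inside the bounds box. The incumbent (lowest
#' NLL over all starts, ties broken by lowest start index) is then
#' refined in a polish stage that restarts the simplex at its own
#' endpoint until no further improvement, guarding against the premature
#' stalls single Nelder-Mead runs are prone to in nine dimensions. The
#' three measurement-error SDs are profiled analytically inside each
#' likelihood evaluation.
#'
#' `n_starts = 50` is the desk-scale default; 2000 starts reproduce a
#' full-scale analysis.
#'
#' @inheritParams negative_log_likelihood
#' @param n_starts number of uniformly drawn starting points.
#' @param seed integer seed making the start draws reproducible.
#' @param bounds bounds table from [default_bounds()]; defaults to the
#'   standard box for the dataset's treatments.
#' @param fix_theta named list of free parameters to pin at given values
#'   (used by sensitivity scans).
#' @param start optional named theta list; when supplied it is used as an
#'   additional first starting point.
#' @param control passed to [stats::optim()]; defaults to
#'   `maxit = 5000`, `reltol = 1e-8` per start.
#' @param polish_maxeval evaluation budget for the polish stage: the
#'   lowest-NLL start (converged or stalled) is refined by Nelder-Mead
#'   runs restarted at their own endpoint until a restart brings no
#'   further improvement. Set to 0 to skip polishing, in which case the
#'   best cleanly converged start is returned unrefined.
#' @return An object of class `theta_estimate`: list with `theta` (all
#'   model parameters, estimated and pinned), `sigmas`, `nll`, `model`,
#'   `fixed`, `bounds` and `diagnostics` (start counts, convergence,
#'   best start index, seed).
#' @export
fit_mle <- function(dataset, fixed, n_starts = 50L, seed = 1L,
                    bounds = NULL, model = c("delay", "instant"),
                    fix_theta = list(), start = NULL,
                    control = list(maxit = 5000, reltol = 1e-8),
                    polish_maxeval = 20000L) {
  if (is.null(control$maxit)) control$maxit <- 5000
  if (is.null(control$reltol)) control$reltol <- 1e-8
  model <- match.arg(model)
  fixed <- check_fixed(fixed)
  validate_dataset(dataset)
  treatments <- unique(dataset$treatment)
  if (is.null(bounds)) bounds <- default_bounds(treatments)
  all_names <- theta_parameter_names(treatments, model)
  if (length(bad <- setdiff(names(fix_theta), all_names)))
    stop("cannot pin unknown parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  free <- setdiff(all_names, names(fix_theta))
  if (length(miss <- setdiff(free, bounds$param)))
    stop("bounds table lacks parameter(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  obj <- make_objective(dataset, fixed, bounds, free, fix_theta, model)
  # seed only when random starts are drawn: refinement-only calls (e.g.
  # inside the bootstrap) must not disturb the caller's RNG stream
  if (n_starts > 0) set.seed(as.integer(seed))
  starts <- draw_starts(as.integer(n_starts), bounds, free)
  if (!is.null(start))
    starts <- rbind(vapply(free, function(nm) start[[nm]], numeric(1)),
                    starts)
  if (nrow(starts) == 0L)
    stop("no starting points (n_starts = 0 and no 'start')", call. = FALSE)
  if (nrow(starts) == 1L && !is.null(start) && polish_maxeval > 0) {
    # refinement-only mode (bootstrap replicates, sensitivity scans):
    # restarted Nelder-Mead from the supplied estimates, no random starts
    z0 <- theta_to_z(as.list(starts[1L, ]), bounds, free)
    pol <- optim_restarts(z0, obj,
                          control = list(maxit = polish_maxeval,
                                         reltol = control$reltol,
                                         improve_tol = control$improve_tol))
    if (!is.finite(pol$value))
      stop("optimization failure: the likelihood could not be evaluated ",
           "near the supplied start", call. = FALSE)
    # a budget-limited refinement that is still descending is returned
    # as-is (flagged unpolished): it starts from the best estimates, so
    # discarding it would bias resampling toward easy datasets
    theta <- z_to_theta(pol$par, bounds, free, fix_theta)
    nll <- negative_log_likelihood(theta, dataset, fixed, model = model)
    return(structure(list(
      theta = theta[all_names], sigmas = attr(nll, "sigmas"),
      nll = as.numeric(nll), parts = attr(nll, "parts"),
      model = model, fixed = fixed, bounds = bounds,
      free = free, fix_theta = fix_theta,
      diagnostics = list(n_starts = 1L, n_converged = 1L,
                         best_start = 1L,
                         polished = pol$convergence == 0L,
                         seed = as.integer(seed))),
      class = "theta_estimate"))
  }
  fits <- vector("list", nrow(starts))
  for (k in seq_len(nrow(starts))) {
    z0 <- theta_to_z(as.list(starts[k, ]), bounds, free)
    fits[[k]] <- tryCatch(
      optim(z0, obj, method = "Nelder-Mead", control = control),
      error = function(e) list(par = z0, value = Inf, convergence = 99L))
  }
  conv <- vapply(fits, function(f) f$convergence == 0L, logical(1))
  vals <- vapply(fits, function(f) f$value, numeric(1))
  if (!any(is.finite(vals)) ||
      (polish_maxeval <= 0 && !any(conv & is.finite(vals))))
    stop("optimization failure: none of the ", nrow(starts),
         " starts converged cleanly", call. = FALSE)
  if (polish_maxeval > 0) {
    # candidates = lowest NLLs over all starts (a stalled run still
    # marks a good basin); the top three are refined by restarted
    # Nelder-Mead and the best refined value wins
    cand <- order(vals)[seq_len(min(3L, sum(is.finite(vals))))]
    pols <- lapply(cand, function(k)
      optim_restarts(fits[[k]]$par, obj,
                     control = list(maxit = polish_maxeval,
                                    reltol = control$reltol,
                                    improve_tol = control$improve_tol)))
    pvals <- vapply(pols, function(pp) pp$value, numeric(1))
    pol <- pols[[which.min(pvals)]]
    best <- cand[which.min(pvals)]
    if (pol$convergence != 0L && !any(conv & is.finite(vals)))
      stop("optimization failure: no start converged cleanly and the ",
           "polish stage did not stabilise", call. = FALSE)
    zbest <- pol$par
    polished <- pol$convergence == 0L
  } else {
    ok <- which(conv & is.finite(vals))
    best <- ok[which.min(vals[ok])]
    zbest <- fits[[best]]$par
    polished <- FALSE
  }
  theta <- z_to_theta(zbest, bounds, free, fix_theta)
  nll <- negative_log_likelihood(theta, dataset, fixed, model = model)
  structure(list(
    theta = theta[all_names], sigmas = attr(nll, "sigmas"),
    nll = as.numeric(nll), parts = attr(nll, "parts"),
    model = model, fixed = fixed, bounds = bounds,
    free = free, fix_theta = fix_theta,
    diagnostics = list(n_starts = nrow(starts), n_converged = sum(conv),
                       best_start = best, polished = polished,
                       seed = as.integer(seed))),
    class = "theta_estimate")
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat(sprintf("MLE fit (%s-lysis model), NLL = %.3f\n",
              if (x$model == "delay") "delayed" else "instantaneous",
              x$nll))
  est <- unlist(x$theta)
  for (nm in names(est))
    cat(sprintf("  %-12s %s%.6g\n", nm,
                if (nm %in% names(x$fix_theta)) "[fixed] " else "", est[nm]))
  cat(sprintf("  sigmas: P = %.3g, g = %.3g, q = %.3g\n",
              x$sigmas[["P"]], x$sigmas[["g"]], x$sigmas[["q"]]))
  d <- x$diagnostics
  cat(sprintf("  %d/%d starts converged; best was start %d (seed %d)\n",
              d$n_converged, d$n_starts, d$best_start, d$seed))
  invisible(x)
}

#' Profile likelihood over the (b, B) plane
#'
#' Fixes the fusion probability `b` and the burst size `B` to each cell
#' of a grid and maximises the likelihood over all remaining parameters,
#' starting each cell's Nelder-Mead run from `start`. On data generated
#' by the model the resulting landscape shows a flat valley along
#' contours of constant `b * B`: rescaling the (unobserved) virion
#' density maps one cell onto another, so only the product is
#' identifiable. This is the diagnostic that motivates fixing `B` in
#' [fit_mle()].
#'
#' @inheritParams fit_mle
#' @param b_grid,B_grid numeric vectors; the grid is their outer product.
#' @param start named theta list used as the common starting point.
#' @return Data frame with columns `b`, `B`, `product`, `nll`,
#'   `converged`.
#' @export
profile_bB <- function(dataset, fixed, b_grid, B_grid, start,
                       bounds = NULL, model = "delay",
                       control = list(maxit = 5000, reltol = 1e-8)) {
  fixed <- check_fixed(fixed)
  validate_dataset(dataset)
  treatments <- unique(dataset$treatment)
  if (is.null(bounds)) bounds <- default_bounds(treatments)
  all_names <- theta_parameter_names(treatments, model)
  free <- setdiff(all_names, "b")
  cells <- expand.grid(b = b_grid, B = B_grid)
  cells$product <- cells$b * cells$B
  cells$nll <- NA_real_
  cells$converged <- FALSE
  for (i in seq_len(nrow(cells))) {
    fx <- fixed
    fx$B <- cells$B[i]
    obj <- make_objective(dataset, fx, bounds, free,
                          list(b = cells$b[i]), model)
    z0 <- theta_to_z(start, bounds, free)
    ans <- optim_restarts(z0, obj, control)
    cells$nll[i] <- ans$value
    cells$converged[i] <- ans$convergence == 0L
  }
  cells
}

#' AIC comparison of the delayed- and instantaneous-lysis models
#'
#' Fits both model variants to the same dataset (same multi-start
#' protocol and seed) and returns `AIC(delayed) - AIC(instantaneous)`
#' with `AIC = 2k + 2 NLL`, where `k` counts the estimated parameters
#' (the free `theta` entries plus the three error SDs; the lysis rate
#' `tau` is counted only for the delayed model). Negative values favour
#' the delayed-lysis model.
#'
#' @inheritParams fit_mle
#' @return List with `fit_delay`, `fit_instant`, `aic_delay`,
#'   `aic_instant` and `delta_aic`.
#' @export
compare_models <- function(dataset, fixed, n_starts = 20L, seed = 1L,
                           bounds = NULL, start = NULL,
                           control = list(maxit = 5000, reltol = 1e-8)) {
  fit_d <- fit_mle(dataset, fixed, n_starts = n_starts, seed = seed,
                   bounds = bounds, model = "delay", start = start,
                   control = control)
  start_i <- if (!is.null(start)) start[setdiff(names(start), "tau")]
  fit_i <- fit_mle(dataset, fixed, n_starts = n_starts, seed = seed,
                   bounds = bounds, model = "instant", start = start_i,
                   control = control)
  k_d <- length(fit_d$free) + 3
  k_i <- length(fit_i$free) + 3
  aic_d <- 2 * k_d + 2 * fit_d$nll
  aic_i <- 2 * k_i + 2 * fit_i$nll
  list(fit_delay = fit_d, fit_instant = fit_i,
       aic_delay = aic_d, aic_instant = aic_i,
       delta_aic = aic_d - aic_i)
}

#' Sensitivity of the estimates to a parameter held fixed
#'
#' Re-runs the optimization with one parameter pinned to each value in
#' `values`, starting from the reference fit, and reports the
#' re-estimated parameters together with their relative variation with
#' respect to the reference. Typical uses: scanning the burst size `B`
#' (all estimates except `b` should be stable, with `b * B` and the
#' reproduction numbers unchanged) or the adsorption rate `a`.
#'
#' @param dataset a `phage_dataset`.
#' @param reference a `theta_estimate` from [fit_mle()].
#' @param param name of the parameter to scan: a free `theta` entry or
#'   `"B"`.
#' @param values numeric vector of values to pin `param` at.
#' @param control passed to [stats::optim()].
#' @return Data frame, one row per value: the pinned value, re-estimated
#'   parameters, `nll`, and `rel_<name>` columns with relative changes.
#' @export
sensitivity_scan <- function(dataset, reference, param, values,
                             control = list(maxit = 5000, reltol = 1e-8)) {
  stopifnot(inherits(reference, "theta_estimate"))
  rows <- vector("list", length(values))
  ref_est <- unlist(reference$theta[reference$free])
  for (i in seq_along(values)) {
    v <- values[i]
    if (param == "B") {
      fx <- reference$fixed
      fx$B <- v
      fit <- fit_mle(dataset, fx, n_starts = 0L,
                     seed = reference$diagnostics$seed,
                     bounds = reference$bounds, model = reference$model,
                     fix_theta = reference$fix_theta,
                     start = reference$theta, control = control)
    } else if (param %in% reference$free) {
      pin <- reference$fix_theta
      pin[[param]] <- v
      fit <- fit_mle(dataset, reference$fixed, n_starts = 0L,
                     seed = reference$diagnostics$seed,
                     bounds = reference$bounds, model = reference$model,
                     fix_theta = pin, start = reference$theta,
                     control = control)
    } else {
      stop("'param' must be \"B\" or one of the free parameters: ",
           paste(reference$free, collapse = ", "), call. = FALSE)
    }
    est <- unlist(fit$theta)[names(reference$theta)]
    rel <- (unlist(fit$theta[reference$free]) - ref_est) / ref_est
    rel <- rel[setdiff(names(rel), param)]
    rows[[i]] <- data.frame(value = v, t(est), nll = fit$nll,
                            t(setNames(rel, paste0("rel_", names(rel)))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
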