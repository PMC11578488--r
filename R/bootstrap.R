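# AICc of a fitted arima object (k = p + q + innovation variance).
arima_aicc <- function(fit, n) {
  k <- length(fit$coef) + 1
  fit$aic + 2 * k * (k + 1) / max(n - k - 1, 1)
}

# Fit one ARMA(p, q) to a centred residual series; returns NULL when the
# fit fails or is non-invertible / non-stationary.
fit_one_arma <- function(x, p, q) {
  fit <- tryCatch(
    suppressWarnings(arima(x, order = c(p, 0L, q), include.mean = FALSE,
                           transform.pars = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  ar <- if (p > 0) fit$coef[seq_len(p)] else numeric(0)
  ma <- if (q > 0) fit$coef[p + seq_len(q)] else numeric(0)
  if (any(!is.finite(c(ar, ma))) || !is.finite(fit$sigma2)) return(NULL)
  tol <- 1e-6
  if (p > 0 && any(Mod(polyroot(c(1, -ar))) <= 1 + tol)) return(NULL)
  if (q > 0 && any(Mod(polyroot(c(1, ma))) <= 1 + tol)) return(NULL)
  list(order = c(p = p, q = q), ar = unname(ar), ma = unname(ma),
       sigma2 = fit$sigma2, aicc = arima_aicc(fit, length(x)))
}

# Select an ARMA model for a centred residual series over p, q <= max_order
# by AICc; falls back to white noise when nothing else fits.
select_arma <- function(x, max_order = 3L) {
  best <- NULL
  for (p in 0:max_order) for (q in 0:max_order) {
    if (p == 0L && q == 0L) {
      # white-noise baseline; exact Gaussian likelihood, same AICc scale
      n <- length(x)
      s2 <- max(mean(x^2), .Machine$double.xmin)
      cand <- list(order = c(p = 0L, q = 0L), ar = numeric(0),
                   ma = numeric(0), sigma2 = s2,
                   aicc = n * (log(2 * pi) + log(s2) + 1) + 2 +
                     4 / max(n - 2, 1))
    } else {
      if (length(x) <= p + q + 2L) next
      cand <- fit_one_arma(x, p, q)
    }
    if (!is.null(cand) && (is.null(best) || cand$aicc < best$aicc))
      best <- cand
  }
  best
}

#' Fit ARMA models to the residuals of the best fit
#'
#' For each chemostat and each of the three responses, computes the
#' residuals between the observed logits and the best-fit deterministic
#' trajectory, centres them, and fits an ARMA model (orders selected by
#' corrected AIC over `p, q <= 3`, stationarity and invertibility
#' enforced; series too short for a candidate order fall back to smaller
#' orders, ultimately white noise). These models capture the serial
#' dependence of the measurement errors and drive the Sieve bootstrap.
#'
#' @param dataset a `phage_dataset`.
#' @param best_fit a `theta_estimate` from [fit_mle()].
#' @param max_order maximum AR and MA order considered.
#' @return A list of class `residual_models`; each element has
#'   `treatment`, `chemostat`, `response`, `order`, `ar`, `ma`,
#'   `sigma2`, `mean` (the centring constant) and `n`.
#' @export
fit_residual_models <- function(dataset, best_fit, max_order = 3L) {
  stopifnot(inherits(best_fit, "theta_estimate"))
  validate_dataset(dataset)
  layout <- prepare_layout(dataset)
  models <- list()
  for (trt in names(layout)) {
    lay <- layout[[trt]]
    pred <- predicted_logits(theta_to_params(best_fit$theta, best_fit$fixed,
                                             best_fit$model),
                             best_fit$theta[[paste0("P0_", trt)]],
                             best_fit$theta[["p0"]], lay$tgrid,
                             best_fit$model)
    d <- dataset[dataset$treatment == trt, ]
    for (ch in unique(d$chemostat)) {
      sel <- d$chemostat == ch
      idx <- lay$idx[sel][order(d$time_h[sel])]
      for (r in c("P", "g", "q")) {
        obs <- d[[paste0("logit_", r)]][sel][order(d$time_h[sel])]
        e <- obs - pred[idx, r]
        ok <- !is.na(e)
        ctr <- mean(e[ok])
        m <- select_arma(e[ok] - ctr, max_order)
        models[[length(models) + 1L]] <-
          c(list(treatment = trt, chemostat = ch, response = r,
                 mean = ctr, n = sum(ok), na_pattern = !ok), m)
      }
    }
  }
  structure(models, class = "residual_models")
}

#' @export
print.residual_models <- function(x, ...) {
  cat(sprintf("%d residual ARMA models (per chemostat x response)\n",
              length(x)))
  for (m in x)
    cat(sprintf("  %s/%s %s: ARMA(%d,%d), sigma2 = %.3g\n",
                m$treatment, m$chemostat, m$response,
                m$order[["p"]], m$order[["q"]], m$sigma2))
  invisible(x)
}

# Simulate one residual series from a fitted ARMA model (Gaussian
# innovations, 50-step burn-in discarded by arima.sim's n.start).
simulate_residuals <- function(m) {
  if (m$n == 0L) return(numeric(0))
  if (m$order[["p"]] == 0L && m$order[["q"]] == 0L)
    return(rnorm(m$n, sd = sqrt(m$sigma2)))
  model <- list()
  if (m$order[["p"]] > 0L) model$ar <- m$ar
  if (m$order[["q"]] > 0L) model$ma <- m$ma
  as.numeric(arima.sim(model = model, n = m$n, n.start = 50L,
                       sd = sqrt(m$sigma2)))
}

#' Percentile confidence intervals from bootstrap draws
#'
#' @param draws data frame of bootstrap re-estimates (one row per
#'   replicate, numeric columns).
#' @param level confidence level, default 0.95.
#' @return Data frame with columns `param`, `lower`, `upper`.
#' @export
ci_from_draws <- function(draws, level = 0.95) {
  if (is.null(draws) || nrow(draws) < 2L)
    stop("need at least two bootstrap draws for an interval", call. = FALSE)
  if (!is.finite(level) || level <= 0 || level > 1)
    stop("'level' must lie in (0, 1]", call. = FALSE)
  a <- (1 - level) / 2
  num <- names(draws)[vapply(draws, is.numeric, logical(1))]
  data.frame(
    param = num,
    lower = vapply(num, function(nm)
      unname(quantile(draws[[nm]], a, na.rm = TRUE)), numeric(1)),
    upper = vapply(num, function(nm)
      unname(quantile(draws[[nm]], 1 - a, na.rm = TRUE)), numeric(1)),
    row.names = NULL)
}

#' Sieve-bootstrap confidence intervals for the full two-step estimation
#'
#' Repeats, `n_boot` times: (i) rebuild a dataset by adding ARMA-simulated
#' residuals (plus each series' centring constant, preserving the
#' missingness pattern) to the best-fit deterministic trajectories;
#' (ii) re-run the two-step estimation on it — [estimate_alphas()] first,
#' then a single Nelder-Mead refinement started from the best MLE
#' estimates with the reactivation rates fixed to the replicate's step-1
#' values. Replicates whose step-1 estimate is invalid or whose
#' optimization does not converge cleanly are dropped and counted.
#' Percentile intervals are computed from the joint draws.
#'
#' @param dataset a `phage_dataset`.
#' @param best_fit a `theta_estimate` from [fit_mle()].
#' @param resid_models optional precomputed [fit_residual_models()]
#'   output.
#' @param n_boot number of bootstrap datasets (200 is the desk-scale
#'   default; 10000 reproduces a full-scale analysis).
#' @param seed integer seed.
#' @param level confidence level for the percentile intervals.
#' @param prevalence_threshold passed to [estimate_alphas()].
#' @param control passed to [stats::optim()]; the default relative
#'   tolerance is looser than [fit_mle()]'s because across-replicate
#'   variation, not optimizer precision, drives the interval widths.
#' @return An object of class `bootstrap_result`: list with `draws` (one
#'   row per successful replicate: `alpha_w`, `alpha_m`, the free
#'   parameters, the error SDs and `nll`), `ci`, `n_requested`,
#'   `n_successful`, `level` and `seed`.
#' @export
sieve_bootstrap <- function(dataset, best_fit, resid_models = NULL,
                            n_boot = 200L, seed = 1L, level = 0.95,
                            prevalence_threshold = 0.95,
                            control = list(maxit = 5000, reltol = 1e-6)) {
  stopifnot(inherits(best_fit, "theta_estimate"))
  validate_dataset(dataset)
  n_boot <- as.integer(n_boot)
  if (is.null(resid_models))
    resid_models <- fit_residual_models(dataset, best_fit)
  layout <- prepare_layout(dataset)
  params_best <- theta_to_params(best_fit$theta, best_fit$fixed,
                                 best_fit$model)
  pred <- lapply(names(layout), function(trt)
    predicted_logits(params_best, best_fit$theta[[paste0("P0_", trt)]],
                     best_fit$theta[["p0"]], layout[[trt]]$tgrid,
                     best_fit$model))
  names(pred) <- names(layout)
  skeleton <- dataset[order(dataset$treatment, dataset$chemostat,
                            dataset$time_h), ]
  draws <- list()
  n_failed <- 0L
  set.seed(as.integer(seed))
  for (bi in seq_len(n_boot)) {
    boot <- skeleton
    for (m in resid_models) {
      sel <- boot$treatment == m$treatment & boot$chemostat == m$chemostat
      col <- paste0("logit_", m$response)
      fitted <- pred[[m$treatment]][
        match(boot$time_h[sel], layout[[m$treatment]]$tgrid), m$response]
      newv <- rep(NA_real_, sum(sel))
      newv[!m$na_pattern] <- fitted[!m$na_pattern] + m$mean +
        simulate_residuals(m)
      boot[[col]][sel] <- newv
    }
    est <- tryCatch({
      al <- estimate_alphas(boot, prevalence_threshold,
                            method = if (!is.null(best_fit$alpha_method))
                              best_fit$alpha_method else "joint")
      if (!al$valid) stop("invalid step-1 estimate")
      fx <- best_fit$fixed
      fx$alpha_w <- al$alpha_w
      fx$alpha_m <- al$alpha_m
      fit <- fit_mle(boot, fx, n_starts = 0L,
                     seed = best_fit$diagnostics$seed,
                     bounds = best_fit$bounds, model = best_fit$model,
                     fix_theta = best_fit$fix_theta,
                     start = best_fit$theta, control = control,
                     polish_maxeval = if (is.null(control$maxit)) 5000L
                                      else control$maxit)
      c(alpha_w = al$alpha_w, alpha_m = al$alpha_m,
        unlist(fit$theta[fit$free]),
        sigma_P = fit$sigmas[["P"]], sigma_g = fit$sigmas[["g"]],
        sigma_q = fit$sigmas[["q"]], nll = fit$nll)
    }, error = function(e) NULL)
    if (is.null(est)) n_failed <- n_failed + 1L
    else draws[[length(draws) + 1L]] <- est
  }
  if (n_boot > 0L && !length(draws))
    stop("bootstrap failure: all ", n_boot, " replicates failed",
         call. = FALSE)
  draws_df <- if (length(draws))
    as.data.frame(do.call(rbind, draws)) else NULL
  ci <- if (!is.null(draws_df) && nrow(draws_df) >= 2L)
    ci_from_draws(draws_df[setdiff(names(draws_df), "nll")], level)
  else NULL
  structure(list(draws = draws_df, ci = ci, n_requested = n_boot,
                 n_successful = length(draws), level = level,
                 seed = as.integer(seed)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Sieve bootstrap: %d/%d replicates successful\n",
              x$n_successful, x$n_requested))
  if (!is.null(x$ci)) {
    cat(sprintf("%d%% percentile intervals:\n", round(100 * x$level)))
    for (i in seq_len(nrow(x$ci)))
      cat(sprintf("  %-10s [%.4g, %.4g]\n", x$ci$param[i],
                  x$ci$lower[i], x$ci$upper[i]))
  }
  invisible(x)
}
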