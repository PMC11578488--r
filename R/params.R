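#' Strain life-history traits
#'
#' A temperate-phage strain is characterised by two traits: the rate
#' `alpha` at which its prophage reactivates (excises and commits the host
#' to lysis, per hour) and the probability `phi` that an infection ends in
#' lysogenization rather than an immediate lytic cycle.
#'
#' @param alpha prophage reactivation (induction) rate, per hour; `>= 0`.
#' @param phi probability of lysogenization upon infection, in `[0, 1]`.
#' @return An object of class `strain_traits` (a named list).
#' @examples
#' strain_traits(alpha = 7e-3, phi = 0.2)
#' @export
strain_traits <- function(alpha, phi) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(phi), length(phi) == 1L)
  if (!is.finite(alpha) || alpha < 0)
    stop("'alpha' must be a finite non-negative rate (h^-1)", call. = FALSE)
  if (!is.finite(phi) || phi < 0 || phi > 1)
    stop("'phi' must be a probability in [0, 1]", call. = FALSE)
  structure(list(alpha = alpha, phi = phi), class = "strain_traits")
}

#' Parameters shared by both phage strains and the host
#'
#' @param a adsorption rate of free virions onto cells (h^-1 cell^-1).
#' @param b probability of fusion (genome injection) upon adsorption.
#' @param tau lysis rate (h^-1); `1/tau` is the mean lysis time.
#' @param B burst size (virions released per lysed cell).
#' @param r bacterial intrinsic growth rate (h^-1).
#' @param K carrying capacity of the bacterial population (cells).
#' @param delta chemostat dilution rate (h^-1).
#' @return An object of class `shared_params` (a named list).
#' @export
shared_params <- function(a, b, tau, B, r, K, delta) {
  v <- c(a = a, b = b, tau = tau, B = B, r = r, K = K, delta = delta)
  if (!all(is.finite(v)) || any(v < 0))
    stop("all shared parameters must be finite and non-negative",
         call. = FALSE)
  if (b > 1) stop("'b' is a probability and must be <= 1", call. = FALSE)
  if (K <= 0) stop("'K' must be positive", call. = FALSE)
  structure(as.list(v), class = "shared_params")
}

#' Full model parameterisation
#'
#' Bundles the wildtype traits, the mutant traits and the shared parameters.
#' The focal biological setting has `phi_m < phi_w` (the mutant lysogenizes
#' less) and `alpha_m > alpha_w` (it reactivates more), but any valid traits
#' are accepted.
#'
#' @param wildtype,mutant [strain_traits()] objects.
#' @param shared a [shared_params()] object.
#' @return An object of class `model_params`.
#' @seealso [default_params()] for the simulation-study parameter set.
#' @export
model_params <- function(wildtype, mutant, shared) {
  stopifnot(inherits(wildtype, "strain_traits"),
            inherits(mutant, "strain_traits"),
            inherits(shared, "shared_params"))
  structure(list(wildtype = wildtype, mutant = mutant, shared = shared),
            class = "model_params")
}

#' Simulation-study parameter set
#'
#' The parameter values used throughout the package's simulation study:
#' `alpha_w = 7e-3`, `alpha_m = 2e-2`, `phi_w = 0.2`, `phi_m = 2e-2`,
#' `a = 3e-9`, `b = 0.1`, `B = 80`, \code{r = 1.4}, `tau = 1.5`, `K = 1e9`,
#' `delta = 0.8` (rates per hour, densities in cells).
#'
#' @param ... named overrides for any of the eleven values above, e.g.
#'   `default_params(tau = 1.5, b = 0.05)`.
#' @return A [model_params()] object.
#' @export
default_params <- function(...) {
  v <- list(alpha_w = 7e-3, alpha_m = 2e-2, phi_w = 0.2, phi_m = 2e-2,
            a = 3e-9, b = 0.1, B = 80, r = 1.4, tau = 1.5, K = 1e9,
            delta = 0.8)
  ov <- list(...)
  bad <- setdiff(names(ov), names(v))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  v[names(ov)] <- ov
  model_params(
    wildtype = strain_traits(v$alpha_w, v$phi_w),
    mutant   = strain_traits(v$alpha_m, v$phi_m),
    shared   = shared_params(v$a, v$b, v$tau, v$B, v$r, v$K, v$delta)
  )
}

#' @export
print.model_params <- function(x, ...) {
  s <- x$shared
  cat("Two-strain temperate-phage model parameters\n")
  cat(sprintf("  wildtype: alpha = %g /h, phi = %g\n",
              x$wildtype$alpha, x$wildtype$phi))
  cat(sprintf("  mutant:   alpha = %g /h, phi = %g\n",
              x$mutant$alpha, x$mutant$phi))
  cat(sprintf("  shared:   a = %g, b = %g, tau = %g, B = %g,\n",
              s$a, s$b, s$tau, s$B))
  cat(sprintf("            r = %g, K = %g, delta = %g\n", s$r, s$K, s$delta))
  invisible(x)
}

# Flat named vector of the 11 parameter values (internal convenience).
params_vector <- function(params) {
  stopifnot(inherits(params, "model_params"))
  s <- params$shared
  c(alpha_w = params$wildtype$alpha, alpha_m = params$mutant$alpha,
    phi_w = params$wildtype$phi, phi_m = params$mutant$phi,
    a = s$a, b = s$b, tau = s$tau, B = s$B, r = s$r, K = s$K,
    delta = s$delta)
}

#' Phenotypic differences between the strains
#'
#' `delta_alpha` is `alpha_m - alpha_w`, `delta_phi` is `phi_m - phi_w`.
#'
#' @param params a [model_params()] object.
#' @return Named numeric vector with elements `delta_alpha`, `delta_phi`.
#' @export
trait_deltas <- function(params) {
  stopifnot(inherits(params, "model_params"))
  c(delta_alpha = params$mutant$alpha - params$wildtype$alpha,
    delta_phi   = params$mutant$phi - params$wildtype$phi)
}
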