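#' Logit and inverse logit with boundary clipping
#'
#' All observed responses in this package live on the log-odds (logit)
#' scale. Frequencies exactly at 0 or 1 have infinite log-odds; `logit()`
#' therefore clips its argument to `[eps, 1 - eps]` before transforming,
#' and records which elements were clipped in the `"clipped"` attribute
#' (omitted when nothing was clipped). Values outside `[0, 1]` are an
#' error, not a clipping case.
#'
#' @param x numeric vector of frequencies in `[0, 1]` (`NA` allowed).
#' @param eps clipping half-width, default `1e-12`.
#' @return `logit()`: log-odds of the clipped frequencies; `inv_logit()`:
#'   frequencies in `(0, 1)`.
#' @examples
#' logit(0.5)                 # 0
#' inv_logit(logit(0.3))      # 0.3
#' attr(logit(1), "clipped")  # TRUE for that element
#' @export
logit <- function(x, eps = 1e-12) {
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad))
    stop("frequencies must lie in [0, 1]; offending value(s): ",
         paste(utils::head(x[bad], 3L), collapse = ", "), call. = FALSE)
  clipped <- !is.na(x) & (x < eps | x > 1 - eps)
  y <- qlogis(pmin(pmax(x, eps), 1 - eps))
  if (any(clipped)) attr(y, "clipped") <- clipped
  y
}

#' @rdname logit
#' @export
inv_logit <- function(x) {
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  plogis(x)
}
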