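#' Design of a simulated chemostat experiment
#'
#' Describes the layout of a synthetic dataset: the treatments (initial
#' prevalences), the number of replicate chemostats per treatment, the
#' sampling grid and the standard deviations of the logit-scale Gaussian
#' measurement errors on the three responses (prevalence `P`, infected
#' mutant frequency `g`, free-virus mutant frequency `q`).
#'
#' Defaults mirror the package's simulation study: an epidemic treatment
#' started at 1% prevalence and an endemic treatment at 99%, four
#' chemostats each, hourly sampling from 1 to 60 h (sampling starts at
#' 1 h because `g` is undefined before any `Y` cells or virions exist),
#' and measurement error SD 0.5 on all three logit responses. The studied
#' quantity/quality grid (sampling every 10 h vs hourly; SD 0.5 vs 0.01)
#' is reached by overriding `times` and the SDs.
#'
#' @param treatments named numeric vector of initial prevalences.
#' @param replicates chemostats per treatment.
#' @param times increasing sampling times (h), all `> 0`.
#' @param sigma_P,sigma_g,sigma_q measurement-error SDs (logit scale).
#' @param mutant_share initial mutant share among lysogens.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(treatments = c(epidemic = 0.01, endemic = 0.99),
                        replicates = 4L,
                        times = seq(1, 60, by = 1),
                        sigma_P = 0.5, sigma_g = 0.5, sigma_q = 0.5,
                        mutant_share = 0.5) {
  if (is.null(names(treatments)) || any(!nzchar(names(treatments))))
    stop("'treatments' must be a named vector of initial prevalences",
         call. = FALSE)
  if (any(treatments < 0 | treatments > 1))
    stop("treatment prevalences must lie in [0, 1]", call. = FALSE)
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L)
    stop("'replicates' must be a positive integer", call. = FALSE)
  if (length(times) < 2L || any(diff(times) <= 0) || times[1L] <= 0)
    stop("'times' must be increasing and start after t = 0", call. = FALSE)
  sds <- c(sigma_P, sigma_g, sigma_q)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("noise SDs must be finite and non-negative", call. = FALSE)
  structure(list(treatments = treatments, replicates = replicates,
                 times = times, sigma_P = sigma_P, sigma_g = sigma_g,
                 sigma_q = sigma_q, mutant_share = mutant_share),
            class = "design_spec")
}

# Deterministic substream seed for (treatment i, replicate j, response r).
# Additive scheme keeps existing replicates unchanged when more are added.
substream_seed <- function(seed, i, j, r) {
  (seed + 7919L * i + 101L * j + 13L * r) %% .Machine$integer.max
}

#' Generate a synthetic dataset
#'
#' For each treatment the deterministic model is simulated once from
#' [initial_state()]; each replicate chemostat is then obtained by adding
#' independent Gaussian noise, per response and per time point, to the
#' deterministic logit trajectories of `P`, `g` and `q`. Noise is added on
#' the logit scale (not to the raw frequencies), matching the assumed
#' measurement-error model of the likelihood. Non-finite logits (empty
#' compartments) are recorded as missing.
#'
#' Each (treatment, replicate, response) triple draws from its own seeded
#' substream, so adding replicates does not perturb existing ones.
#'
#' @param params a [model_params()] object.
#' @param design a [design_spec()].
#' @param seed integer seed for the noise.
#' @return A `phage_dataset`: a data frame with columns `treatment`,
#'   `chemostat`, `time_h`, `logit_P`, `logit_g`, `logit_q`, carrying the
#'   generating `params`, `design` and `seed` in its `"provenance"`
#'   attribute.
#' @examples
#' d <- generate_dataset(default_params(),
#'                       design_spec(times = seq(1, 60, by = 10)), seed = 1)
#' head(d)
#' @export
generate_dataset <- function(params, design = design_spec(), seed = 1L) {
  stopifnot(inherits(params, "model_params"), inherits(design, "design_spec"))
  seed <- as.integer(seed)
  sim_times <- c(0, design$times)
  sds <- c(P = design$sigma_P, g = design$sigma_g, q = design$sigma_q)
  rows <- vector("list", length(design$treatments) * design$replicates)
  k <- 0L
  for (i in seq_along(design$treatments)) {
    trt <- names(design$treatments)[i]
    tr <- simulate_model(params,
                         initial_state(design$treatments[[i]],
                                       design$mutant_share, params),
                         times = sim_times)
    tr <- tr[tr$time > 0, ]
    det <- cbind(P = logit(tr$P), g = logit(tr$g), q = logit(tr$q))
    det[!is.finite(det)] <- NA_real_
    for (j in seq_len(design$replicates)) {
      noisy <- det
      for (r in 1:3) {
        set.seed(substream_seed(seed, i, j, r))
        noisy[, r] <- det[, r] + rnorm(nrow(det), sd = sds[[r]])
      }
      k <- k + 1L
      rows[[k]] <- data.frame(treatment = trt, chemostat = j,
                              time_h = tr$time,
                              logit_P = noisy[, "P"],
                              logit_g = noisy[, "g"],
                              logit_q = noisy[, "q"])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "provenance") <- list(params = params, design = design,
                                  seed = seed)
  class(out) <- c("phage_dataset", "data.frame")
  out
}

dataset_columns <- c("treatment", "chemostat", "time_h",
                     "logit_P", "logit_g", "logit_q")

# Validate the dataset schema; returns the data invisibly or stops with a
# message naming the offending row.
validate_dataset <- function(d) {
  missing_cols <- setdiff(dataset_columns, names(d))
  if (length(missing_cols))
    stop("dataset is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(d) == 0L) stop("dataset contains no rows", call. = FALSE)
  for (col in c("time_h", "logit_P", "logit_g", "logit_q")) {
    if (!is.numeric(d[[col]]))
      stop(sprintf("column '%s' must be numeric (first bad row: %d)",
                   col, which(!is.na(d[[col]]) &
                                is.na(suppressWarnings(
                                  as.numeric(d[[col]]))))[1L]),
           call. = FALSE)
  }
  key <- paste(d$treatment, d$chemostat, d$time_h, sep = "\r")
  if (anyDuplicated(key))
    stop(sprintf("duplicate (treatment, chemostat, time) at row %d",
                 anyDuplicated(key)), call. = FALSE)
  invisible(d)
}

#' Read / write a dataset CSV
#'
#' The on-disk schema is one row per chemostat per sampling time, columns
#' `treatment`, `chemostat`, `time_h`, `logit_P`, `logit_g`, `logit_q`
#' (missing observations empty). `read_dataset()` validates the schema and
#' errors with the offending column/row; writing then reading a dataset
#' reproduces it.
#'
#' @param path CSV file path.
#' @return `read_dataset()`: a `phage_dataset` with provenance
#'   `"external"`; `write_dataset()`: `path`, invisibly.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                error = function(e)
                  stop("cannot parse '", path, "': ", conditionMessage(e),
                       call. = FALSE))
  validate_dataset(d)
  d <- d[order(d$treatment, d$chemostat, d$time_h), dataset_columns]
  rownames(d) <- NULL
  attr(d, "provenance") <- "external"
  class(d) <- c("phage_dataset", "data.frame")
  d
}

#' @rdname read_dataset
#' @param dataset a `phage_dataset` (or conforming data frame).
#' @export
write_dataset <- function(dataset, path) {
  validate_dataset(dataset)
  write.csv(as.data.frame(dataset)[, dataset_columns], path,
            row.names = FALSE, na = "")
  invisible(path)
}

# Deterministic logit trajectories underlying a dataset's layout: one
# simulation per treatment, evaluated on that treatment's observed grid.
# Returns a data.frame keyed like the dataset (chemostat-independent).
deterministic_logits <- function(params, dataset,
                                 treatments = NULL, mutant_share = 0.5,
                                 model = "delay") {
  validate_dataset(dataset)
  if (is.null(treatments)) {
    prov <- attr(dataset, "provenance")
    if (is.list(prov)) {
      treatments <- prov$design$treatments
      mutant_share <- prov$design$mutant_share
    } else {
      stop("treatment initial prevalences are required for an external ",
           "dataset", call. = FALSE)
    }
  }
  out <- lapply(unique(dataset$treatment), function(trt) {
    if (is.na(match(trt, names(treatments))))
      stop("no initial prevalence supplied for treatment '", trt, "'",
           call. = FALSE)
    tgrid <- sort(unique(dataset$time_h[dataset$treatment == trt]))
    sim <- if (model == "delay")
      simulate_model(params, initial_state(treatments[[trt]],
                                           mutant_share, params),
                     times = c(0, tgrid))
    else
      simulate_original_model(params,
                              initial_state(treatments[[trt]],
                                            mutant_share, params),
                              times = c(0, tgrid))
    sim <- sim[sim$time > 0, ]
    data.frame(treatment = trt, time_h = sim$time,
               logit_P = as.numeric(logit(sim$P)),
               logit_g = as.numeric(logit(sim$g)),
               logit_q = as.numeric(logit(sim$q)))
  })
  do.call(rbind, out)
}
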