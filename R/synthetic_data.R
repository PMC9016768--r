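#' Plate-reader noise model
#'
#' Describes replicate-to-replicate and read noise applied on top of the
#' deterministic simulator: one multiplicative lognormal factor per
#' replicate (pipetting / lysate batch variability, the dominant term),
#' additive Gaussian read noise per time point, a constant
#' autofluorescence baseline, and optional injected outliers (a whole
#' replicate scaled by `outlier_factor`, motivating the Grubbs stage).
#'
#' @param cv_mult coefficient of variation of the per-replicate
#'   multiplicative factor (lognormal, meanlog 0).
#' @param sigma_add additive read noise sd per time point (uM).
#' @param baseline autofluorescence offset (uM).
#' @param outlier_rate probability a replicate is replaced by an outlier.
#' @param outlier_factor multiplicative magnitude of injected outliers.
#' @param seed integer seed for the dataset-level random stream.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(cv_mult = 0.1, sigma_add = 0.01, baseline = 0.02,
                        outlier_rate = 0, outlier_factor = 5, seed = 1L) {
  vals <- c(cv_mult, sigma_add, baseline, outlier_rate, outlier_factor)
  if (any(!is.finite(vals)) || any(vals < 0) || outlier_rate > 1) {
    stop("noise parameters must be >= 0 and outlier_rate <= 1", call. = FALSE)
  }
  structure(list(cv_mult = cv_mult, sigma_add = sigma_add,
                 baseline = baseline, outlier_rate = outlier_rate,
                 outlier_factor = outlier_factor, seed = as.integer(seed)),
            class = "noise_model")
}

# stable 31-bit hash of a label, for hierarchical stream splitting:
# dataset seed -> condition substream -> replicate substream, so adding a
# condition never perturbs the draws of another
.label_seed <- function(seed, label, replicate) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483563
  as.integer((h + seed * 7919 + replicate * 104729) %% 2147483563)
}

#' Generate a replicated noisy time-course dataset
#'
#' Runs the deterministic simulator once per condition, then applies the
#' noise model independently per replicate: trajectory scaled by a
#' lognormal factor (sd on log scale `sqrt(log(1 + cv^2))`), optionally
#' replaced by an `outlier_factor`-scaled outlier, plus baseline and
#' per-point additive noise, clipped at zero. Fully reproducible from the
#' noise model's seed; random streams are split hierarchically by
#' condition label and replicate id.
#'
#' @param conditions a `condition_set`.
#' @param params a `kinetic_params`; defaults to the mode of the first spec.
#' @param noise a `noise_model`.
#' @return a `timecourse_dataset`: data.frame with columns `condition`,
#'   `replicate`, `time_min`, `deGFP_uM`, carrying the generating
#'   `condition_set`, parameter digest, noise model and seed as attributes.
#' @export
generate_dataset <- function(conditions,
                             params = default_params(conditions$specs[[1]]$mode),
                             noise = noise_model()) {
  stopifnot(inherits(conditions, "condition_set"),
            inherits(noise, "noise_model"))
  sdlog <- sqrt(log(1 + noise$cv_mult^2))
  nrep <- conditions$replicates
  pieces <- lapply(conditions$specs, function(sp) {
    traj <- simulate_txtl(sp, params)
    nt <- length(traj$times)
    reps <- lapply(seq_len(nrep), function(r) {
      set.seed(.label_seed(noise$seed, sp$label, r))
      fac <- if (noise$cv_mult > 0) stats::rlnorm(1, 0, sdlog) else 1
      is_out <- noise$outlier_rate > 0 &&
        stats::runif(1) < noise$outlier_rate
      y <- traj$observed_deGFP * fac
      if (is_out) y <- y * noise$outlier_factor
      y <- y + noise$baseline +
        if (noise$sigma_add > 0) stats::rnorm(nt, 0, noise$sigma_add) else 0
      data.frame(condition = sp$label, replicate = r,
                 time_min = traj$times, deGFP_uM = pmax(y, 0))
    })
    do.call(rbind, reps)
  })
  ds <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  structure(ds,
            class = c("timecourse_dataset", "data.frame"),
            conditions = conditions,
            params_digest = params_digest(params),
            noise = noise,
            seed = noise$seed)
}

#' Digest of a parameter set, recorded in dataset provenance
#' @param params a `kinetic_params`.
#' @return md5 character string.
#' @export
params_digest <- function(params) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(params), digits = NA), f)
  unname(tools::md5sum(f))
}

#' End-point table of a time-course dataset
#'
#' One row per (condition, replicate) with the deGFP level at the final
#' time point — the batch-experiment readout. Errors if replicate time
#' grids are ragged. When the dataset carries its generating
#' `condition_set`, an `n_inputs` column is added for class grouping.
#'
#' @param ds a `timecourse_dataset` (or plain data.frame with the same
#'   columns).
#' @return data.frame with columns `condition`, `replicate`,
#'   `endpoint_uM` and, when available, `n_inputs`.
#' @export
endpoints_table <- function(ds) {
  req <- c("condition", "replicate", "time_min", "deGFP_uM")
  if (!all(req %in% names(ds))) {
    stop("dataset must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(ds)) stop("empty dataset", call. = FALSE)
  key <- interaction(ds$condition, ds$replicate, drop = TRUE)
  grids <- tapply(ds$time_min, key, function(t) paste(t, collapse = ","))
  if (length(unique(grids)) != 1L) {
    stop("ragged time grids across (condition, replicate) groups",
         call. = FALSE)
  }
  tmax <- max(ds$time_min)
  sel <- ds$time_min == tmax
  last <- data.frame(condition = ds$condition[sel],
                     replicate = ds$replicate[sel],
                     endpoint_uM = ds$deGFP_uM[sel])
  last <- last[order(match(last$condition, unique(ds$condition)),
                     last$replicate), ]
  rownames(last) <- NULL
  conds <- attr(ds, "conditions")
  if (!is.null(conds)) {
    ni <- vapply(conds$specs, n_inputs, 0L)
    last$n_inputs <- unname(ni[last$condition])
    attr(last, "conditions") <- conds
  }
  last
}

#' Full bundle of emulated study datasets
#'
#' Generates the complete set of built-in layouts with the calibrated
#' default parameters and default noise: the direct-expression
#' weighted-sum design (all 8 input combinations), the sigma28-coupled
#' design, and the perceptron design at each of the three anti-sigma28
#' levels (0, 0.5, 1 uM). Three replicates per condition. Deterministic
#' given the seed.
#'
#' @param seed integer seed.
#' @param replicates replicates per condition (>= 3 by default).
#' @param noise a `noise_model`; its seed field is overridden per dataset
#'   from `seed`.
#' @return named list of `timecourse_dataset`s: `direct_wso`,
#'   `coupled_wso`, `perceptron_0`, `perceptron_0.5`, `perceptron_1`.
#' @export
fixture_bundle <- function(seed = 1L, replicates = 3L, noise = noise_model()) {
  specs <- list(
    direct_wso = list(fix = "direct_wso", inh = 0),
    coupled_wso = list(fix = "coupled_wso", inh = 0),
    `perceptron_0` = list(fix = "perceptron", inh = 0),
    `perceptron_0.5` = list(fix = "perceptron", inh = 0.5),
    `perceptron_1` = list(fix = "perceptron", inh = 1))
  out <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    cs <- wso_fixture(s$fix, inhibitor_conc = s$inh, replicates = replicates)
    nm <- noise
    nm$seed <- as.integer((seed * 1000003 + i * 9176) %% 2147483563)
    generate_dataset(cs, default_params(cs$specs[[1]]$mode), nm)
  })
  names(out) <- names(specs)
  out
}
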