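#' Least-squares estimate of the linear scaling factors
#'
#' Fits the linear weighted-sum model's per-pair scaling factors to
#' single-input end-point data, the fit-then-predict workflow: parameters
#' are estimated from single-input reactions only and later used to
#' predict multi-input behaviour. Because each single-input observation
#' involves exactly one term of the sum, ordinary least squares separates
#' per pair into the closed form
#' \deqn{\hat{s}_i = \sum_r y_r (x_i w_i)_r / \sum_r (x_i w_i)_r^2}
#' over the replicates r of pair i. Replicates are pooled, unweighted
#' (homoscedastic least squares).
#'
#' @param endpoints end-point table (`condition`, `replicate`,
#'   `endpoint_uM`), restricted to single-input conditions, e.g. from
#'   [endpoints_table()].
#' @param conditions the `condition_set` describing those conditions;
#'   defaults to the set attached to `endpoints`' parent dataset when
#'   `endpoints` is a `timecourse_dataset`.
#' @return a `wso_fit`: list with `model` (`linear_wso`), `residuals`,
#'   `rss`, `n_obs`, `source_digest`.
#' @export
fit_linear <- function(endpoints, conditions = attr(endpoints, "conditions")) {
  prep <- .prep_single_input(endpoints, conditions)
  scale <- numeric(3)
  for (i in 1:3) {
    sel <- prep$pair == i
    d <- prep$design[sel]
    y <- prep$y[sel]
    if (any(d == 0 & y > 0)) {
      stop("nonzero endpoint with zero input*weight design for pair ", i,
           ": unexplainable signal", call. = FALSE)
    }
    scale[i] <- if (sum(d^2) > 0) max(sum(y * d) / sum(d^2), 0) else 0
  }
  model <- linear_wso(scale)
  fitted <- scale[prep$pair] * prep$design
  res <- prep$y - fitted
  structure(list(model = model, residuals = res, rss = sum(res^2),
                 n_obs = length(res), source_digest = prep$digest),
            class = "wso_fit")
}

.prep_single_input <- function(endpoints, conditions) {
  if (inherits(endpoints, "timecourse_dataset")) {
    if (is.null(conditions)) conditions <- attr(endpoints, "conditions")
    endpoints <- endpoints_table(endpoints)
  }
  if (is.null(conditions)) {
    stop("a condition_set is required to map conditions to designs",
         call. = FALSE)
  }
  specs <- conditions$specs
  ni <- vapply(specs, n_inputs, 0L)
  singles <- names(specs)[ni == 1L]
  endpoints <- endpoints[endpoints$condition %in% names(specs), , drop = FALSE]
  ep_ni <- ni[endpoints$condition]
  if (any(ep_ni != 1L)) {
    # restrict silently only when the table also covers non-single rows of
    # a full design; a table of exclusively wrong rows is an error
    endpoints <- endpoints[ep_ni == 1L, , drop = FALSE]
    if (!nrow(endpoints)) {
      stop("no single-input conditions in the endpoint table", call. = FALSE)
    }
  }
  pair_of <- vapply(specs, function(sp) {
    p <- which(sp$input_conc > 0)
    if (length(p) == 1L) p else NA_integer_
  }, 0L)
  pair <- pair_of[endpoints$condition]
  missing <- setdiff(1:3, unique(pair))
  if (length(missing)) {
    stop("no single-input observations for pair(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  design <- vapply(endpoints$condition, function(cl) {
    sp <- specs[[cl]]
    p <- which(sp$input_conc > 0)
    sp$input_conc[p] * sp$weight_conc[p]
  }, 0.0)
  spec1 <- specs[[1]]
  list(pair = unname(pair), design = unname(design), y = endpoints$endpoint_uM,
       specs = specs, reporter_conc = spec1$reporter_conc,
       digest = paste0("endpoints-n", nrow(endpoints)))
}

#' @export
print.wso_fit <- function(x, ...) {
  cat("<wso_fit>", class(x$model)[1], "- n_obs:", x$n_obs,
      " rss:", signif(x$rss, 5), "\n")
  cat("  scale:", paste(signif(x$model$scale, 5), collapse = ", "), "\n")
  if (inherits(x$model, "coupled_wso")) {
    cat("  act_gain:", signif(x$model$act_gain, 5),
        " act_half:", signif(x$model$act_half, 5), "\n")
  }
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}

#' Nonlinear least-squares fit of the coupled weighted-sum model
#'
#' Fits scaling factors and, unless constrained, the activation gain and
#' half-activation constant of the sigma28-coupled model to single-input
#' end-point data by Levenberg-Marquardt least squares with multiple
#' seeded starts (8 by default). All parameters are bounded below by zero;
#' `act_half` is bounded within `[1e-3, 1e3]` times the data-derived scale.
#' Note that the activation form is invariant under rescaling all scaling
#' factors and `act_half` by a common factor, so without an
#' `act_constraints` entry only `act_gain` and the ratios
#' `scale / act_half` are identifiable; with a single design point per
#' pair the configuration is further under-determined and the fit records
#' a warning in the result.
#'
#' @inheritParams fit_linear
#' @param act_constraints optional named list fixing any of `act_gain`,
#'   `act_half`, `hill`.
#' @param n_starts number of multi-start initialisations.
#' @param seed seed for the start jitter (deterministic fit).
#' @return a `wso_fit` with a `coupled_wso` model; fields as in
#'   [fit_linear()] plus `warnings`.
#' @export
fit_coupled <- function(endpoints, conditions = attr(endpoints, "conditions"),
                        act_constraints = NULL, n_starts = 8L, seed = 1L) {
  prep <- .prep_single_input(endpoints, conditions)
  y <- prep$y
  rep_c <- prep$reporter_conc
  if (rep_c <= 0) stop("coupled fit requires a reporter template",
                       call. = FALSE)
  hill <- act_constraints$hill %||% 1
  fix_gain <- act_constraints$act_gain
  fix_half <- act_constraints$act_half
  warnings <- character()

  if (all(y == 0)) {
    model <- coupled_wso(c(0, 0, 0), act_gain = fix_gain %||% 1,
                         act_half = fix_half %||% 1, hill = hill,
                         reporter_ref = rep_c)
    return(structure(list(model = model, residuals = y, rss = 0,
                          n_obs = length(y), warnings = warnings,
                          source_digest = prep$digest),
                     class = "wso_fit"))
  }

  n_design <- length(unique(paste(prep$pair, prep$design)))
  if (n_design <= 3 && is.null(fix_half) && is.null(fix_gain)) {
    warnings <- c(warnings,
                  "single design point per pair with free activation parameters: not identifiable")
  }

  ymax <- max(y)
  pred_fn <- function(par) {
    scale <- par[1:3]
    g <- if (is.null(fix_gain)) par[["act_gain"]] else fix_gain
    K <- if (is.null(fix_half)) par[["act_half"]] else fix_half
    S <- scale[prep$pair] * prep$design
    g * S^hill / (K^hill + S^hill)
  }
  resid_fn <- function(par) y - pred_fn(abs(par))

  base_scale <- vapply(1:3, function(i) {
    sel <- prep$pair == i
    mean(y[sel]) / mean(prep$design[sel]) / max(ymax, 1e-12)
  }, 0.0)
  base_start <- c(base_scale,
                  if (is.null(fix_gain)) c(act_gain = 2 * ymax),
                  if (is.null(fix_half)) c(act_half = 1))

  lower <- rep(0, length(base_start))
  upper <- rep(Inf, length(base_start))
  if (!is.null(names(base_start)) && "act_half" %in% names(base_start)) {
    i <- which(names(base_start) == "act_half")
    lower[i] <- 1e-3
    upper[i] <- 1e3
  }

  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- base_start * stats::rlnorm(length(base_start), 0,
                                        if (s == 1) 0 else 0.7)
    start <- pmin(pmax(start, lower + 1e-9), pmin(upper, 1e6))
    fit <- try(minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15) {
      best <- list(par = abs(fit$par), rss = rss)
    }
  }
  if (is.null(best)) stop("coupled fit failed for all starts", call. = FALSE)

  par <- best$par
  model <- coupled_wso(scale = par[1:3],
                       act_gain = if (is.null(fix_gain)) par[["act_gain"]]
                                  else fix_gain,
                       act_half = if (is.null(fix_half)) par[["act_half"]]
                                  else fix_half,
                       hill = hill, reporter_ref = rep_c)
  res <- y - pred_fn(par)
  structure(list(model = model, residuals = res, rss = sum(res^2),
                 n_obs = length(y), warnings = warnings,
                 source_digest = prep$digest),
            class = "wso_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit on single-input data and predict the full design
#'
#' The complete fit-then-predict workflow on one dataset: estimates the
#' weighted-sum model from the single-input conditions, predicts every
#' condition of the design, and joins predictions with observed end-point
#' statistics. For coupled-mode data the activation gain defaults to twice
#' the largest single-input response (at the dataset's reporter
#' concentration) with `act_half = 1`; since only the gain-relative
#' response shapes multi-input curvature, this fixes the otherwise
#' non-identifiable activation scale.
#'
#' @param ds a `timecourse_dataset` covering all 8 input combinations.
#' @param act_constraints optional activation constraints forwarded to
#'   [fit_coupled()] (coupled mode only).
#' @return data.frame with one row per condition: `condition`, `n_inputs`,
#'   `observed_mean_uM`, `observed_sd_uM`, `predicted_uM`; the `wso_fit`
#'   is attached as attribute `fit`.
#' @export
fit_predict_report <- function(ds, act_constraints = NULL) {
  conditions <- attr(ds, "conditions")
  if (is.null(conditions)) {
    stop("dataset must carry its generating condition_set", call. = FALSE)
  }
  ni <- vapply(conditions$specs, n_inputs, 0L)
  if (!all(ni[ni == 1L] >= 1) || sum(ni == 1L) != 3L ||
      length(conditions$specs) < 8L) {
    stop("dataset must cover the full 8-combination design ",
         "(missing single-input conditions block fitting)", call. = FALSE)
  }
  ep <- endpoints_table(ds)
  mode <- conditions$specs[[1]]$mode
  fit <- if (mode == "direct") {
    fit_linear(ep, conditions)
  } else {
    if (is.null(act_constraints)) {
      singles <- names(ni)[ni == 1L]
      ymax <- max(ep$endpoint_uM[ep$condition %in% singles])
      act_constraints <- list(act_gain = 2 * ymax, act_half = 1)
    }
    fit_coupled(ep, conditions, act_constraints = act_constraints)
  }
  pred <- predict_table(fit$model, conditions)
  obs_mean <- tapply(ep$endpoint_uM, ep$condition, mean)
  obs_sd <- tapply(ep$endpoint_uM, ep$condition, stats::sd)
  out <- data.frame(
    condition = pred$condition,
    n_inputs = pred$n_inputs,
    observed_mean_uM = unname(obs_mean[pred$condition]),
    observed_sd_uM = unname(obs_sd[pred$condition]),
    predicted_uM = pred$predicted_uM,
    row.names = NULL)
  attr(out, "fit") <- fit
  out
}
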