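#' Rudimentary linear weighted-sum model
#'
#' The phenomenological model of the direct-expression weighted-sum
#' operation: each input-weight pair contributes a term equal to its input
#' template concentration `x` (nM) times its weight template concentration
#' `w` (nM) times a per-pair scaling factor that lumps transcription,
#' translation and RNA-binding efficiency. The predicted deGFP output is
#' the sum over the three pairs,
#' \deqn{y = \alpha x_1 w_1 + \beta x_2 w_2 + \gamma x_3 w_3 .}
#' The model is fitted on single-input end-point data only, so multi-input
#' predictions assume no resource burden — they upper-bound the
#' mechanistic output whenever burden is active.
#'
#' @param scale numeric length-3 vector of scaling factors (uM per nM^2),
#'   all >= 0.
#' @return an object of class `linear_wso`.
#' @export
linear_wso <- function(scale = c(0, 0, 0)) {
  scale <- as.numeric(scale)
  if (length(scale) != 3L || any(!is.finite(scale)) || any(scale < 0)) {
    stop("scale must be 3 finite non-negative values", call. = FALSE)
  }
  structure(list(scale = scale), class = "linear_wso")
}

#' Sigma28-coupled weighted-sum model
#'
#' Extension of the linear model for the coupled circuit: the weighted sum
#' `S` now stands for produced sigma28, which activates reporter
#' expression through a saturating (generalised hyperbolic) activation,
#' \deqn{y = g \frac{S^h}{K^h + S^h} \cdot \frac{reporter}{reporter_{ref}},}
#' with gain `g` proportional to the reporter template concentration
#' (referenced to `reporter_ref`), half-activation constant `K` and Hill
#' coefficient `h` (default 1, the minimal saturating activator).
#'
#' @param scale per-pair scaling factors (sigma28 surrogate per nM^2).
#' @param act_gain maximal reporter output at the reference reporter
#'   concentration (uM).
#' @param act_half weighted-sum level at half-maximal activation.
#' @param hill Hill coefficient (default 1).
#' @param reporter_ref reporter template concentration the gain refers to
#'   (nM).
#' @return an object of class `coupled_wso`.
#' @export
coupled_wso <- function(scale = c(0, 0, 0), act_gain = 1, act_half = 1,
                        hill = 1, reporter_ref = 15) {
  scale <- as.numeric(scale)
  vals <- c(scale, act_gain, act_half, hill, reporter_ref)
  if (length(scale) != 3L || any(!is.finite(vals)) ||
      any(c(scale, act_gain, act_half) < 0) || hill <= 0 ||
      reporter_ref <= 0) {
    stop("invalid coupled model parameters", call. = FALSE)
  }
  structure(list(scale = scale, act_gain = act_gain, act_half = act_half,
                 hill = hill, reporter_ref = reporter_ref),
            class = "coupled_wso")
}

#' Weighted sum of a reaction spec under a model's scaling factors
#' @keywords internal
wso_sum <- function(scale, spec) {
  sum(scale * spec$input_conc * spec$weight_conc)
}

#' Predict end-point output of a reaction
#'
#' @param object a `linear_wso` or `coupled_wso` model.
#' @param spec a `reaction_spec` in the matching mode.
#' @param ... unused.
#' @return predicted deGFP end point (uM).
#' @export
predict.linear_wso <- function(object, spec, ...) {
  stopifnot(inherits(spec, "reaction_spec"))
  if (spec$mode != "direct") {
    stop("linear model predicts direct-mode reactions only", call. = FALSE)
  }
  wso_sum(object$scale, spec)
}

#' @rdname predict.linear_wso
#' @export
predict.coupled_wso <- function(object, spec, ...) {
  stopifnot(inherits(spec, "reaction_spec"))
  if (spec$mode != "coupled") {
    stop("coupled model predicts coupled-mode reactions only", call. = FALSE)
  }
  S <- wso_sum(object$scale, spec)
  if (S == 0) return(0)
  act <- S^object$hill / (object$act_half^object$hill + S^object$hill)
  object$act_gain * act * spec$reporter_conc / object$reporter_ref
}

#' Predictions for every condition of a set
#'
#' @param model a `linear_wso` or `coupled_wso`.
#' @param conditions a `condition_set` whose specs match the model's mode.
#' @return data.frame with columns `condition`, `n_inputs`,
#'   `predicted_uM`.
#' @export
predict_table <- function(model, conditions) {
  stopifnot(inherits(conditions, "condition_set"))
  data.frame(
    condition = vapply(conditions$specs, `[[`, "", "label"),
    n_inputs = vapply(conditions$specs, n_inputs, 0L),
    predicted_uM = vapply(conditions$specs,
                          function(sp) predict(model, sp), 0.0),
    row.names = NULL)
}

#' Serialize a weighted-sum model to JSON
#'
#' @param model a `linear_wso` or `coupled_wso`, typically from a fit.
#' @param path output path.
#' @param provenance optional list (e.g. source dataset digest) stored
#'   alongside the parameters.
#' @return `path`, invisibly.
#' @export
write_wso_model <- function(model, path, provenance = NULL) {
  x <- c(list(class = class(model)[1]), unclass(model))
  if (!is.null(provenance)) x$provenance <- provenance
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_wso_model
#' @export
read_wso_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- x$class
  x$class <- NULL
  x$provenance <- NULL
  if (identical(cls, "linear_wso")) linear_wso(x$scale)
  else do.call(coupled_wso, x)
}
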