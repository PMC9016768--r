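#' Perceptron configuration
#'
#' Holds the abstract perceptron layer of the circuit: the weights (the
#' weight-template concentrations), the bias term `b` implemented
#' chemically by the anti-sigma28 concentration, the deGFP readout
#' threshold, and the slope converting inhibitor concentration (uM) to
#' the magnitude of the (non-positive) bias. The perceptron computes
#' \eqn{f(\sum_i w_i x_i + b)} with a Heaviside-style threshold `f`.
#'
#' @param weights length-3 numeric, abstract weights per pair.
#' @param bias bias term, in the units of the weighted sum; must be <= 0
#'   when derived from a positive inhibitor concentration.
#' @param readout_threshold deGFP ON/OFF threshold (uM), default 0.5.
#' @param bias_slope conversion from inhibitor uM to |bias|. The shipped
#'   default (9, weighted-sum units per uM anti-sigma28) was calibrated
#'   once against the default simulator bundle so the abstract threshold
#'   and the mechanistic readout agree on all three logic regimes.
#' @return an object of class `perceptron_config`.
#' @export
perceptron_config <- function(weights = c(0.6, 0.6, 0.8), bias = 0,
                              readout_threshold = 0.5, bias_slope = 9) {
  weights <- as.numeric(weights)
  if (length(weights) != 3L || any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be 3 finite non-negative values", call. = FALSE)
  }
  if (!(readout_threshold > 0)) {
    stop("readout_threshold must be > 0", call. = FALSE)
  }
  if (bias > 0) stop("bias must be <= 0 (inhibitor-implemented)",
                     call. = FALSE)
  if (bias_slope < 0) stop("bias_slope must be >= 0", call. = FALSE)
  structure(list(weights = weights, bias = bias,
                 readout_threshold = readout_threshold,
                 bias_slope = bias_slope),
            class = "perceptron_config")
}

#' Perceptron thresholding function
#'
#' The activation function of the perceptron: returns 1 ("ON") iff the
#' weighted sum plus bias is strictly greater than zero, else 0. The
#' strict inequality means a weighted sum exactly cancelled by the bias
#' reads 0.
#'
#' @param weighted_sum value of the weighted sum.
#' @param bias bias term (<= 0 when inhibitor-implemented).
#' @return 0 or 1 (vectorised).
#' @export
threshold_fn <- function(weighted_sum, bias = 0) {
  as.integer(weighted_sum + bias > 0)
}

#' Classify a deGFP end point as ON or OFF
#'
#' Expression is "OFF" when the expressed deGFP concentration is below
#' the threshold (default 0.5 uM); equality reads ON. Note the two
#' strictness conventions of the two layers differ and both are kept as
#' stated: the abstract rule [threshold_fn()] is strictly-greater-than
#' zero, the readout rule here is strictly-below-threshold for OFF.
#'
#' @param endpoint deGFP end point (uM), >= 0.
#' @param threshold readout threshold (uM), default 0.5.
#' @return `"ON"` or `"OFF"` (vectorised).
#' @export
classify_readout <- function(endpoint, threshold = 0.5) {
  if (any(endpoint < 0)) stop("endpoint must be >= 0", call. = FALSE)
  ifelse(endpoint < threshold, "OFF", "ON")
}

#' Target table of an input-count logic function
#'
#' The desired perceptron target for every combination of the three
#' binary inputs: OR targets 1 for at least one present input, MAJORITY
#' for at least two, AND only for all three; the empty combination always
#' targets 0.
#'
#' @param fn one of `"OR"`, `"MAJORITY"`, `"AND"`.
#' @return a `logic_table`: data.frame with columns `in1`, `in2`, `in3`
#'   (0/1), `n_inputs`, `target` (0/1) and a `condition` label matching
#'   [enumerate_input_combinations()].
#' @export
logic_table <- function(fn = c("OR", "MAJORITY", "AND")) {
  fn <- match.arg(fn)
  need <- switch(fn, OR = 1L, MAJORITY = 2L, AND = 3L)
  subsets <- list(integer(0), 1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L),
                  c(1L, 2L, 3L))
  bits <- t(vapply(subsets, function(s) as.integer(1:3 %in% s),
                   integer(3)))
  lab <- vapply(subsets, function(s) {
    if (!length(s)) "none" else paste0("in", paste(s, collapse = "+"))
  }, "")
  out <- data.frame(condition = lab, in1 = bits[, 1], in2 = bits[, 2],
                    in3 = bits[, 3], n_inputs = rowSums(bits),
                    target = as.integer(rowSums(bits) >= need))
  attr(out, "logic_fn") <- fn
  class(out) <- c("logic_table", "data.frame")
  out
}

#' Map an inhibitor concentration to the perceptron bias
#'
#' The chemical implementation of the bias: anti-sigma28 sequesters the
#' weighted-sum output, entering the abstract layer as a negative offset
#' proportional to its concentration.
#'
#' @param inhibitor_conc anti-sigma28 (uM), >= 0.
#' @param config a `perceptron_config` (uses `bias_slope`).
#' @return the (non-positive) bias value.
#' @export
inhibitor_to_bias <- function(inhibitor_conc, config = perceptron_config()) {
  if (any(inhibitor_conc < 0)) stop("inhibitor_conc must be >= 0",
                                    call. = FALSE)
  -config$bias_slope * inhibitor_conc
}

#' Evaluate a logic regime on a measured dataset
#'
#' Classifies the replicate-mean end point of every input combination of
#' a dataset recorded at one inhibitor level and compares the ON/OFF
#' pattern against the target table of a logic function.
#'
#' @param ds a `timecourse_dataset` covering all 8 input combinations at
#'   a single inhibitor concentration.
#' @param fn logic function name (`"OR"`, `"MAJORITY"`, `"AND"`).
#' @param threshold readout threshold (uM).
#' @return a `regime_report`: data.frame with one row per combination
#'   (`condition`, `n_inputs`, `mean_endpoint_uM`, `call`, `target`,
#'   `match`) plus attributes `logic_fn`, `inhibitor_conc` and
#'   `exact_match` (TRUE iff every row matches).
#' @export
evaluate_regime <- function(ds, fn = c("OR", "MAJORITY", "AND"),
                            threshold = 0.5) {
  fn <- match.arg(fn)
  conditions <- attr(ds, "conditions")
  if (is.null(conditions)) {
    stop("dataset must carry its generating condition_set", call. = FALSE)
  }
  lt <- logic_table(fn)
  ep <- endpoints_table(ds)
  means <- tapply(ep$endpoint_uM, ep$condition, mean)
  missing <- setdiff(lt$condition, names(means))
  if (length(missing)) {
    stop("dataset is missing input combinations: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  inh <- unique(vapply(conditions$specs, `[[`, 0.0, "inhibitor_conc"))
  if (length(inh) != 1L) {
    stop("dataset mixes inhibitor levels; evaluate one regime at a time",
         call. = FALSE)
  }
  mean_ep <- unname(means[lt$condition])
  call <- classify_readout(mean_ep, threshold)
  onoff <- as.integer(call == "ON")
  out <- data.frame(condition = lt$condition, n_inputs = lt$n_inputs,
                    mean_endpoint_uM = mean_ep, call = call,
                    target = lt$target, match = onoff == lt$target)
  attr(out, "logic_fn") <- fn
  attr(out, "inhibitor_conc") <- inh
  attr(out, "exact_match") <- all(out$match)
  class(out) <- c("regime_report", "data.frame")
  out
}

#' @export
print.regime_report <- function(x, ...) {
  cat("<regime_report>", attr(x, "logic_fn"), "at",
      attr(x, "inhibitor_conc"), "uM anti-sigma28 - exact match:",
      attr(x, "exact_match"), "\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}
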