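#' Describe one batch TXTL reaction
#'
#' A `reaction_spec` is the declarative description of a single batch
#' cell-free transcription-translation (TXTL) reaction: which trigger
#' ("input") DNA templates are present and at what concentration, the
#' switch ("weight") template pattern, the optional downstream deGFP
#' reporter template, the anti-sigma28 inhibitor concentration, and the
#' sampling schedule.
#'
#' Units are fixed throughout the package: DNA template concentrations in
#' nM, protein concentrations in uM, time in minutes. `mode = "direct"`
#' means the switches translate deGFP directly (no reporter template);
#' `mode = "coupled"` means the switches translate sigma28, which activates
#' transcription of a separate deGFP reporter template.
#'
#' @param input_conc numeric vector of length 3, trigger template
#'   concentration per input-weight pair (nM); 0 means the input is omitted.
#' @param weight_conc numeric vector of length 3, switch template
#'   concentration per pair (nM). All three weights are present in every
#'   reaction of a weighted-sum experiment.
#' @param reporter_conc deGFP reporter template concentration (nM); must be
#'   0 in direct mode.
#' @param inhibitor_conc anti-sigma28 concentration (uM).
#' @param mode `"direct"` or `"coupled"`.
#' @param duration total reaction time (minutes).
#' @param sample_interval sampling interval (minutes); must divide
#'   `duration`.
#' @param temperature_label metadata string; kinetics are not
#'   temperature-parameterised.
#' @param label optional condition label; a default is derived from the
#'   set of present inputs.
#'
#' @return an object of class `reaction_spec`.
#' @export
reaction_spec <- function(input_conc = c(0, 0, 0),
                          weight_conc = c(1, 5, 7.5),
                          reporter_conc = 0,
                          inhibitor_conc = 0,
                          mode = c("direct", "coupled"),
                          duration = 960,
                          sample_interval = 5,
                          temperature_label = "29C",
                          label = NULL) {
  mode <- match.arg(mode)
  input_conc <- as.numeric(input_conc)
  weight_conc <- as.numeric(weight_conc)
  if (length(input_conc) != 3L || length(weight_conc) != 3L) {
    stop("input_conc and weight_conc must each have length 3", call. = FALSE)
  }
  if (any(!is.finite(c(input_conc, weight_conc, reporter_conc,
                       inhibitor_conc))) ||
      any(c(input_conc, weight_conc, reporter_conc, inhibitor_conc) < 0)) {
    stop("all concentrations must be finite and >= 0", call. = FALSE)
  }
  if (mode == "direct" && reporter_conc != 0) {
    stop("direct mode has no reporter template: reporter_conc must be 0",
         call. = FALSE)
  }
  if (!(duration > 0)) stop("duration must be > 0", call. = FALSE)
  if (!(sample_interval > 0) || (duration %% sample_interval) != 0) {
    stop("sample_interval must be > 0 and divide duration", call. = FALSE)
  }
  if (is.null(label)) {
    present <- which(input_conc > 0)
    label <- if (length(present) == 0L) "none" else
      paste0("in", paste(present, collapse = "+"))
  }
  structure(
    list(pair_ids = 1:3,
         input_conc = input_conc,
         weight_conc = weight_conc,
         reporter_conc = as.numeric(reporter_conc),
         inhibitor_conc = as.numeric(inhibitor_conc),
         mode = mode,
         duration = as.numeric(duration),
         sample_interval = as.numeric(sample_interval),
         temperature_label = temperature_label,
         label = label),
    class = "reaction_spec")
}

#' @export
print.reaction_spec <- function(x, ...) {
  cat("<reaction_spec>", x$label, sprintf("[%s mode]\n", x$mode))
  cat("  inputs (nM):   ", paste(x$input_conc, collapse = ", "), "\n")
  cat("  weights (nM):  ", paste(x$weight_conc, collapse = ", "), "\n")
  cat("  reporter (nM): ", x$reporter_conc,
      "  anti-sigma28 (uM): ", x$inhibitor_conc, "\n")
  cat("  schedule:       every", x$sample_interval, "min for",
      x$duration, "min\n")
  invisible(x)
}

#' Number of inputs present in a reaction spec
#' @param spec a `reaction_spec`.
#' @return integer count of nonzero input concentrations.
#' @export
n_inputs <- function(spec) {
  stopifnot(inherits(spec, "reaction_spec"))
  sum(spec$input_conc > 0)
}

#' Bundle reaction specs into a labelled condition set
#'
#' @param specs list of `reaction_spec` objects with unique labels.
#' @param label name for the set.
#' @param replicates replicate count per spec (>= 1).
#' @return an object of class `condition_set`.
#' @export
condition_set <- function(specs, label = "conditions", replicates = 3L) {
  if (!length(specs) || !all(vapply(specs, inherits, TRUE, "reaction_spec"))) {
    stop("specs must be a non-empty list of reaction_spec objects",
         call. = FALSE)
  }
  labs <- vapply(specs, `[[`, "", "label")
  if (anyDuplicated(labs)) {
    stop("spec labels must be unique within a condition set", call. = FALSE)
  }
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  names(specs) <- labs
  structure(list(label = label, specs = specs,
                 replicates = as.integer(replicates)),
            class = "condition_set")
}

#' @export
print.condition_set <- function(x, ...) {
  cat("<condition_set>", x$label, "-", length(x$specs), "conditions x",
      x$replicates, "replicates\n")
  invisible(x)
}

#' Enumerate all input combinations of a three-pair design
#'
#' Expands a template reaction into the full set of 2^3 = 8 input subsets
#' (3 single-, 3 double-, 1 triple-input plus the no-input control), each
#' present input at a common standard concentration. Weights, reporter,
#' inhibitor and schedule are copied from the template.
#'
#' @param spec_template a `reaction_spec` giving the shared layout.
#' @param standard_input_conc concentration (nM) for every present input.
#' @param replicates replicate count recorded in the returned set.
#' @return a `condition_set` of 8 specs, ordered by input count.
#' @export
enumerate_input_combinations <- function(spec_template,
                                         standard_input_conc = 5,
                                         replicates = 3L) {
  stopifnot(inherits(spec_template, "reaction_spec"))
  if (!(standard_input_conc > 0)) {
    stop("standard_input_conc must be > 0", call. = FALSE)
  }
  subsets <- list(integer(0), 1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L),
                  c(1L, 2L, 3L))
  specs <- lapply(subsets, function(s) {
    conc <- c(0, 0, 0)
    conc[s] <- standard_input_conc
    sp <- spec_template
    sp$input_conc <- conc
    sp$label <- if (length(s) == 0L) "none" else
      paste0("in", paste(s, collapse = "+"))
    sp
  })
  condition_set(specs, label = "input_combinations", replicates = replicates)
}

#' Built-in experimental layouts
#'
#' The three condition layouts used throughout the package, matching the
#' study designs the calibrated defaults emulate:
#'
#' * `"direct_wso"`: direct-expression weighted-sum operation; inputs 5 nM,
#'   weight pattern (1, 5, 7.5) nM, no reporter template.
#' * `"coupled_wso"`: sigma28-coupled weighted-sum operation; inputs 5 nM,
#'   weight pattern (0.6, 0.6, 0.8) nM, reporter 15 nM.
#' * `"perceptron"`: as `"coupled_wso"` but with a 12.5 nM reporter
#'   template and anti-sigma28 at one of 0, 0.5 or 1.0 uM.
#'
#' Each layout enumerates all 8 input combinations.
#'
#' @param name one of `"direct_wso"`, `"coupled_wso"`, `"perceptron"`.
#' @param inhibitor_conc anti-sigma28 (uM), used by `"perceptron"` only.
#' @param replicates replicate count recorded in the set.
#' @return a `condition_set`.
#' @export
wso_fixture <- function(name = c("direct_wso", "coupled_wso", "perceptron"),
                        inhibitor_conc = 0, replicates = 3L) {
  name <- match.arg(name)
  template <- switch(
    name,
    direct_wso = reaction_spec(weight_conc = c(1, 5, 7.5),
                               reporter_conc = 0, mode = "direct"),
    coupled_wso = reaction_spec(weight_conc = c(0.6, 0.6, 0.8),
                                reporter_conc = 15, mode = "coupled"),
    perceptron = reaction_spec(weight_conc = c(0.6, 0.6, 0.8),
                               reporter_conc = 12.5,
                               inhibitor_conc = inhibitor_conc,
                               mode = "coupled"))
  cs <- enumerate_input_combinations(template, standard_input_conc = 5,
                                     replicates = replicates)
  cs$label <- name
  cs
}
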