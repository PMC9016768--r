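# config files: format is chosen by extension; JSON and YAML carry the
# same structures
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = jsonlite::read_json(path, simplifyVector = TRUE),
         yaml = ,
         yml = yaml::read_yaml(path),
         stop("unsupported config extension: .", ext, call. = FALSE))
}

write_config <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                     pretty = TRUE),
         yaml = ,
         yml = yaml::write_yaml(x, path, precision = 15L),
         stop("unsupported config extension: .", ext, call. = FALSE))
  invisible(path)
}

.spec_schema <- c("input_conc", "weight_conc", "reporter_conc",
                  "inhibitor_conc", "mode", "duration", "sample_interval")

#' Read and write reaction specs and condition sets
#'
#' Serialises a `reaction_spec` or a whole `condition_set` to JSON or YAML
#' (chosen by file extension) and validates the schema on load: required
#' fields present, concentrations non-negative, mode known, schedule
#' consistent — every rule the constructors enforce.
#'
#' @param spec a `reaction_spec`.
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_reaction_spec <- function(spec, path) {
  stopifnot(inherits(spec, "reaction_spec"))
  write_config(unclass(spec), path)
}

#' @rdname write_reaction_spec
#' @export
read_reaction_spec <- function(path) {
  raw <- read_config(path)
  .spec_from_list(raw, path)
}

.spec_from_list <- function(raw, path = "<list>") {
  missing <- setdiff(.spec_schema, names(raw))
  if (length(missing)) {
    stop("invalid reaction spec in ", path, ": missing field(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  reaction_spec(input_conc = raw$input_conc, weight_conc = raw$weight_conc,
                reporter_conc = raw$reporter_conc,
                inhibitor_conc = raw$inhibitor_conc, mode = raw$mode,
                duration = raw$duration,
                sample_interval = raw$sample_interval,
                temperature_label = raw$temperature_label %||% "29C",
                label = raw$label)
}

#' @rdname write_reaction_spec
#' @param conditions a `condition_set`.
#' @export
write_condition_set <- function(conditions, path) {
  stopifnot(inherits(conditions, "condition_set"))
  write_config(list(label = conditions$label,
                    replicates = conditions$replicates,
                    specs = lapply(conditions$specs, unclass)), path)
}

#' @rdname write_reaction_spec
#' @export
read_condition_set <- function(path) {
  raw <- read_config(path)
  if (is.null(raw$specs)) {
    stop("invalid condition set in ", path, ": missing 'specs'",
         call. = FALSE)
  }
  specs <- lapply(raw$specs, .spec_from_list, path = path)
  condition_set(specs, label = raw$label %||% "conditions",
                replicates = raw$replicates %||% 1L)
}

#' Read and write time-course datasets as tidy CSV
#'
#' Datasets are written as comma-separated UTF-8 with header
#' `condition,replicate,time_min,deGFP_uM` plus a sidecar JSON provenance
#' file (`<path>.provenance.json`) recording the generating condition
#' set, parameter digest, noise model, seed and package version. Existing
#' files are never overwritten unless `overwrite = TRUE`.
#'
#' @param ds a `timecourse_dataset`.
#' @param path CSV output path.
#' @param overwrite allow replacing an existing file.
#' @return `write_dataset` returns `path` invisibly; `read_dataset`
#'   returns a `timecourse_dataset` (with the condition set restored from
#'   the sidecar when present).
#' @export
write_dataset <- function(ds, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    stop("refusing to overwrite ", path, " (use overwrite = TRUE)",
         call. = FALSE)
  }
  utils::write.csv(as.data.frame(ds)[, c("condition", "replicate",
                                         "time_min", "deGFP_uM")],
                   path, row.names = FALSE)
  conds <- attr(ds, "conditions")
  prov <- list(
    package_version = as.character(utils::packageVersion("txtlperceptron")),
    params_digest = attr(ds, "params_digest"),
    noise = if (!is.null(attr(ds, "noise"))) unclass(attr(ds, "noise")),
    seed = attr(ds, "seed"),
    conditions = if (!is.null(conds)) list(label = conds$label,
                                           replicates = conds$replicates,
                                           specs = lapply(conds$specs,
                                                          unclass)))
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  ds <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("condition", "replicate", "time_min", "deGFP_uM")
  missing <- setdiff(req, names(ds))
  if (length(missing)) {
    stop("dataset ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  prov_path <- paste0(path, ".provenance.json")
  conds <- NULL
  seed <- NULL
  if (file.exists(prov_path)) {
    prov <- jsonlite::read_json(prov_path, simplifyVector = TRUE)
    seed <- prov$seed
    if (!is.null(prov$conditions)) {
      specs <- lapply(prov$conditions$specs, .spec_from_list,
                      path = prov_path)
      conds <- condition_set(specs, label = prov$conditions$label,
                             replicates = prov$conditions$replicates)
    }
  }
  structure(ds, class = c("timecourse_dataset", "data.frame"),
            conditions = conds, seed = seed)
}

#' Run the full analysis pipeline on one bundle
#'
#' The end-to-end workflow: generate (or accept) the emulated study
#' bundle, compute end points, fit the weighted-sum models on the
#' single-input conditions and predict the full designs, classify each
#' perceptron regime against its logic function, and run the threshold
#' t-tests. Returns everything in memory; pass `out_dir` to also write
#' the report CSVs and a JSON summary.
#'
#' @param seed integer seed for dataset generation.
#' @param bundle optional pre-generated bundle from [fixture_bundle()];
#'   generated from `seed` when omitted.
#' @param out_dir optional output directory for CSV/JSON reports.
#' @param overwrite forwarded to file writing.
#' @return list with `reports` (fit-predict report per weighted-sum
#'   dataset), `regimes` (a `regime_report` per inhibitor level),
#'   `threshold_tests` (one-sided t against the ON threshold per
#'   perceptron condition) and `summary` (regime exact-match flags).
#' @export
run_pipeline <- function(seed = 1L, bundle = NULL, out_dir = NULL,
                         overwrite = FALSE) {
  if (is.null(bundle)) bundle <- fixture_bundle(seed)
  reports <- list(
    direct_wso = fit_predict_report(bundle$direct_wso),
    coupled_wso = fit_predict_report(bundle$coupled_wso))
  regime_fns <- c(`perceptron_0` = "OR", `perceptron_0.5` = "MAJORITY",
                  `perceptron_1` = "AND")
  regimes <- lapply(names(regime_fns), function(nm) {
    evaluate_regime(bundle[[nm]], regime_fns[[nm]])
  })
  names(regimes) <- regime_fns

  threshold_tests <- lapply(names(regime_fns), function(nm) {
    ep <- endpoints_table(bundle[[nm]])
    conds <- unique(ep$condition)
    batch_tests(ep, lapply(conds, function(cl) {
      list(test = "t_greater", conditions = cl, mu0 = 0.5)
    }))
  })
  names(threshold_tests) <- regime_fns

  summary <- lapply(regimes, function(r) {
    list(logic_fn = attr(r, "logic_fn"),
         inhibitor_conc_uM = attr(r, "inhibitor_conc"),
         exact_match = attr(r, "exact_match"))
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(reports)) {
      p <- file.path(out_dir, paste0("report_", nm, ".csv"))
      if (!file.exists(p) || overwrite) {
        utils::write.csv(reports[[nm]], p, row.names = FALSE)
      }
    }
    for (nm in names(regimes)) {
      p <- file.path(out_dir, paste0("regime_", nm, ".csv"))
      if (!file.exists(p) || overwrite) {
        utils::write.csv(as.data.frame(regimes[[nm]]), p, row.names = FALSE)
      }
    }
    jsonlite::write_json(list(seed = seed, regimes = summary),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(reports = reports, regimes = regimes,
       threshold_tests = threshold_tests, summary = summary)
}
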