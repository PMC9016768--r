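#!/usr/bin/env Rscript
# One-time calibration of the shipped default kinetic parameters
# (inst/extdata/params_{direct,coupled}.json). Run from the repository
# root after changing the model structure; the tuned values are written
# back into the JSON configs, which are plain data at run time.
#
# Two coupled tuning loops per mode, iterated jointly (damped, because
# crosstalk couples the pairs):
#   * per-pair translation rates k_tl are tuned so the three single-input
#     endpoints under the full weight pattern are approximately equal
#     (the weight pattern compensating per-pair expression strengths);
#   * the off-diagonal crosstalk efficiencies theta are tuned so the
#     *measured* relative off-target expression (input i with weight j in
#     isolation at pattern concentrations, normalized by the on-target
#     reaction of input i) hits the target orthogonality pattern:
#     at least fivefold reduction for inputs 1 and 3, roughly halved
#     expression for input 2.
#
# For the coupled circuit the single-input tuning targets are sigma28
# totals just below the 0.5 uM titration point (all singles OFF at
# 0.5 uM anti-sigma28, doubles above 0.5, triple above 1 uM) — the
# operating points of the OR / MAJORITY / AND regimes.

suppressMessages(library(txtlperceptron))

# measured relative off-target targets (row = input, col = weight)
ratio_target <- rbind(c(1, 0.14, 0.17),
                      c(0.50, 1, 0.48),
                      c(0.16, 0.13, 1))

as_params <- function(raw) {
  p <- raw
  p$comment <- NULL
  p$theta <- txtlperceptron:::as_theta_matrix(p$theta)
  do.call(kinetic_params, p)
}

measure_singles <- function(params, key, mode) {
  cs <- wso_fixture(key)
  vapply(paste0("in", 1:3), function(l) {
    tr <- simulate_txtl(cs$specs[[l]], params)
    if (mode == "direct") endpoint(tr)
    else tr$states[nrow(tr$states), "P"]  # total sigma28
  }, 0.0)
}

measure_isolation <- function(params, mode) {
  w <- if (mode == "direct") c(1, 5, 7.5) else c(0.6, 0.6, 0.8)
  rep_c <- if (mode == "direct") 0 else 7.5
  M <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    inp <- c(0, 0, 0); inp[i] <- 5
    wc <- c(0, 0, 0); wc[j] <- w[j]
    sp <- reaction_spec(inp, wc, reporter_conc = rep_c, mode = mode)
    M[i, j] <- endpoint(simulate_txtl(sp, params))
  }
  M / diag(M)
}

tune_mode <- function(mode, key, target_single, n_iter = 12) {
  path <- file.path("inst", "extdata", paste0("params_", mode, ".json"))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (it in seq_len(n_iter)) {
    params <- as_params(raw)
    got <- measure_singles(params, key, mode)
    R <- measure_isolation(params, mode)
    cat(sprintf("[%s iter %2d] singles: %s | off-target: %s\n", mode, it,
                paste(signif(got, 4), collapse = " "),
                paste(signif(R[row(R) != col(R)], 2), collapse = " ")))
    raw$k_tl <- raw$k_tl * (target_single / got)^0.7
    th <- txtlperceptron:::as_theta_matrix(raw$theta)
    th <- th * (ratio_target / R)^0.7
    th <- pmin(pmax(th, 1e-4), 0.95)
    diag(th) <- 1
    raw$theta <- lapply(1:3, function(i) th[i, ])
  }
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(raw)
}

# slight deliberate asymmetry in targets: equal "within ~20%", not identical
tune_mode("direct", "direct_wso", target_single = c(1.00, 1.05, 0.90))
tune_mode("coupled", "perceptron", target_single = c(0.43, 0.45, 0.41))

# report the resulting perceptron operating points
p <- read_params(file.path("inst", "extdata", "params_coupled.json"))
for (inh in c(0, 0.5, 1)) {
  cs <- wso_fixture("perceptron", inhibitor_conc = inh)
  eps <- vapply(cs$specs, function(sp) endpoint(simulate_txtl(sp, p)), 0.0)
  cat(sprintf("anti-sigma28 %.1f uM endpoints (uM deGFP):\n", inh))
  print(round(eps, 3))
}
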