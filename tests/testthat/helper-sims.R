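# shared deterministic simulations, memoised so several test files can use
# the same trajectories without re-integrating
.sim_cache <- new.env(parent = emptyenv())

det_trajectories <- function(fixture, inhibitor_conc = 0) {
  key <- paste0(fixture, "@", inhibitor_conc)
  if (is.null(.sim_cache[[key]])) {
    cs <- wso_fixture(fixture, inhibitor_conc = inhibitor_conc)
    .sim_cache[[key]] <- lapply(cs$specs, simulate_txtl)
  }
  .sim_cache[[key]]
}

det_endpoints <- function(fixture, inhibitor_conc = 0) {
  vapply(det_trajectories(fixture, inhibitor_conc), endpoint, 0.0)
}

# zero-noise dataset wrapper for a fixture (replicates identical)
zero_noise_dataset <- function(fixture, replicates = 2L, params = NULL) {
  cs <- wso_fixture(fixture, replicates = replicates)
  if (is.null(params)) params <- default_params(cs$specs[[1]]$mode)
  generate_dataset(cs, params,
                   noise_model(cv_mult = 0, sigma_add = 0, baseline = 0,
                               seed = 1L))
}
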