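test_that("no activation pathway means no output", {
  sp <- reaction_spec(input_conc = c(0, 0, 0), mode = "direct",
                      duration = 120, sample_interval = 10)
  p <- default_params("direct")
  expect_equal(p$k_leak, 0)
  traj <- simulate_txtl(sp, p)
  expect_true(all(traj$observed_deGFP == 0))
  expect_equal(endpoint(traj), 0)
})

test_that("overwhelming anti-sigma28 silences the coupled reporter", {
  sp <- reaction_spec(input_conc = c(5, 5, 5), weight_conc = c(0.6, 0.6, 0.8),
                      reporter_conc = 12.5, inhibitor_conc = 50,
                      mode = "coupled")
  expect_lt(endpoint(simulate_txtl(sp)), 1e-3)
})

test_that("adaptive integration agrees with a fixed-step Euler oracle", {
  sp <- reaction_spec(input_conc = c(5, 0, 0), weight_conc = c(1, 5, 7.5),
                      mode = "direct", duration = 60, sample_interval = 5)
  p <- default_params("direct")
  ref <- euler_direct(sp, p, dt = 0.001, t_end = 60)
  got <- endpoint(simulate_txtl(sp, p))
  expect_lt(abs(got - ref) / ref, 1e-3)
})

test_that("endpoint returns the final grid sample", {
  traj <- det_trajectories("direct_wso")[["in1"]]
  expect_equal(endpoint(traj),
               traj$observed_deGFP[length(traj$observed_deGFP)])
  # batch expression is cumulative here (no protein decay), so the
  # endpoint is also the maximum
  expect_equal(endpoint(traj), max(traj$observed_deGFP))
})

test_that("free_sigma28 solves the titration quadratic", {
  expect_equal(free_sigma28(2, 0, 1), 2)
  expect_equal(free_sigma28(0, 5, 1), 0)
  # positive quadratic root vs bisection oracle
  expect_equal(free_sigma28(2, 1, 1), bisect_free_sigma(2, 1, 1),
               tolerance = 1e-12)
  # ultrasensitive regime: just below vs just above the inhibitor pool
  expect_lt(free_sigma28(0.99, 1, 1e-4), 0.01)
  expect_gt(free_sigma28(1.01, 1, 1e-4), 0.009)
  expect_error(free_sigma28(-1, 0, 1), ">= 0")
})

test_that("holoenzyme fraction solves competitive RNAP binding", {
  p <- default_params("coupled")
  expect_equal(holoenzyme28_fraction(0, p), 0)
  # saturation: no sigma70 competitor, overwhelming sigma28
  p_sat <- kinetic_params(sigma70 = 0, rnap_total = 0.1, K28 = 0.1,
                          K70 = 0.02)
  expect_gt(holoenzyme28_fraction(1e4, p_sat), 0.999)
  # finite case with RNAP depletion vs fixed-point oracle
  for (s28 in c(0.05, 0.3, 1.2)) {
    expect_equal(holoenzyme28_fraction(s28, p),
                 fp_holo28(s28, p$rnap_total, p$sigma70, p$K28, p$K70),
                 tolerance = 1e-8)
  }
  # monotone increasing in free sigma28
  fr <- holoenzyme28_fraction(c(0, 0.1, 0.2, 0.5, 1, 2), p)
  expect_true(all(diff(fr) > 0))
  expect_true(all(fr >= 0 & fr < 1))
})

test_that("calibrated defaults give approximately equal single-input levels", {
  eps <- det_endpoints("direct_wso")[paste0("in", 1:3)]
  expect_lt(max(eps) / min(eps), 1.2)
  cps <- det_endpoints("perceptron")[paste0("in", 1:3)]
  expect_lt(max(cps) / min(cps), 1.2)
})

test_that("states stay non-negative and anti-sigma28 is conserved", {
  for (traj in c(det_trajectories("direct_wso")[c("none", "in1", "in1+2+3")],
                 det_trajectories("perceptron", 0.5)[c("in2", "in1+2+3")])) {
    expect_true(all(traj$states >= -1e-8))
  }
  for (lab in c("in1", "in1+2", "in1+2+3")) {
    traj <- det_trajectories("perceptron", 0.5)[[lab]]
    total_anti <- traj$states[, "Af"] + traj$states[, "AB"]
    expect_true(all(abs(total_anti - 0.5) / 0.5 < 1e-6))
  }
})

test_that("endpoint deGFP is non-increasing in inhibitor concentration", {
  eps <- vapply(seq(0, 2, by = 0.25), function(inh) {
    sp <- reaction_spec(input_conc = c(5, 5, 5),
                        weight_conc = c(0.6, 0.6, 0.8),
                        reporter_conc = 12.5, inhibitor_conc = inh,
                        mode = "coupled")
    endpoint(simulate_txtl(sp))
  }, 0.0)
  expect_true(all(diff(eps) <= 1e-9))
})

test_that("resource burden makes multi-input output subadditive", {
  eps <- det_endpoints("direct_wso")
  singles <- eps[paste0("in", 1:3)]
  expect_lt(eps[["in1+2+3"]], sum(singles))
  expect_lt(eps[["in1+2"]], eps[["in1"]] + eps[["in2"]])
  # additivity is recovered exactly when resource consumption is disabled
  p0 <- default_params("direct")
  p0$mu_res <- 0
  cs <- wso_fixture("direct_wso")
  e0 <- vapply(cs$specs[c("in1", "in2", "in3", "in1+2+3")],
               function(sp) endpoint(simulate_txtl(sp, p0)), 0.0)
  expect_equal(e0[["in1+2+3"]], sum(e0[1:3]), tolerance = 1e-6)
})

test_that("output saturates with increasing input concentration", {
  p <- default_params("direct")
  xs <- c(2.5, 5, 10, 20)
  eps <- vapply(xs, function(x) {
    sp <- reaction_spec(input_conc = c(x, 0, 0), weight_conc = c(1, 5, 7.5),
                        mode = "direct")
    endpoint(simulate_txtl(sp, p))
  }, 0.0)
  expect_true(all(diff(eps) > 0))            # non-decreasing in input
  slopes <- diff(eps) / diff(xs)
  expect_true(all(diff(slopes) < 0))         # diminishing returns per nM
})

test_that("tidy export covers every species on the sampling grid", {
  traj <- det_trajectories("perceptron")[["in1"]]
  df <- as.data.frame(traj)
  expect_true(all(c("time_min", "species", "value", "units") %in% names(df)))
  expect_true("observed_deGFP" %in% df$species)
  expect_equal(sum(df$species == "G"), length(traj$times))
})
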