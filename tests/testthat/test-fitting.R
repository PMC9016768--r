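# endpoint table + condition set built directly from a known model, no
# simulator involved
linear_synthetic <- function(scale, noise_fac = NULL, replicates = 3L) {
  cs <- wso_fixture("direct_wso", replicates = replicates)
  m <- linear_wso(scale)
  rows <- lapply(names(cs$specs), function(lab) {
    y <- predict(m, cs$specs[[lab]])
    fac <- if (is.null(noise_fac)) rep(1, replicates) else
      noise_fac(replicates)
    data.frame(condition = lab, replicate = seq_len(replicates),
               endpoint_uM = y * fac)
  })
  list(endpoints = do.call(rbind, rows), conditions = cs)
}

test_that("fit_linear reduces to the mean ratio at one design point", {
  cs <- wso_fixture("direct_wso")
  ep <- data.frame(
    condition = rep(c("in1", "in2", "in3"), each = 3),
    replicate = rep(1:3, 3),
    endpoint_uM = c(0.9, 1.0, 1.1, 0.5, 0.5, 0.5, 2, 2, 2))
  fit <- fit_linear(ep, cs)
  # pair 1: mean 1.0 at x*w = 5*1 -> 0.2
  expect_equal(fit$model$scale[1], 0.2, tolerance = 1e-12)
  expect_equal(fit$model$scale[2], 0.5 / 25, tolerance = 1e-12)
  expect_equal(fit$model$scale[3], 2 / 37.5, tolerance = 1e-12)
  expect_equal(fit$rss, sum((c(0.9, 1, 1.1) - 1)^2), tolerance = 1e-12)
  expect_equal(fit$n_obs, 9L)
})

test_that("fit_linear recovers known scaling factors exactly", {
  truth <- c(0.2, 0.05, 0.027)
  syn <- linear_synthetic(truth)
  fit <- fit_linear(syn$endpoints, syn$conditions)
  expect_equal(fit$model$scale, truth, tolerance = 1e-9)
  expect_lt(fit$rss, 1e-18)
  # all-zero data gives all-zero scales
  syn0 <- linear_synthetic(c(0, 0, 0))
  expect_equal(fit_linear(syn0$endpoints, syn0$conditions)$model$scale,
               c(0, 0, 0))
})

test_that("fit_linear rejects unusable designs", {
  cs <- wso_fixture("direct_wso")
  ep <- data.frame(condition = rep("in1", 3), replicate = 1:3,
                   endpoint_uM = c(1, 1, 1))
  expect_error(fit_linear(ep, cs), "pair")
  # nonzero signal with a zero design value is unexplainable
  zw <- condition_set(lapply(1:3, function(i) {
    inp <- c(0, 0, 0); inp[i] <- 5
    reaction_spec(inp, weight_conc = c(0, 5, 7.5), mode = "direct")
  }))
  ep_bad <- data.frame(condition = c("in1", "in2", "in3"), replicate = 1,
                       endpoint_uM = c(0.5, 0.5, 0.5))
  expect_error(fit_linear(ep_bad, zw), "unexplainable")
})

test_that("fit_linear is unbiased across seeded noisy datasets", {
  truth <- c(0.2, 0.05, 0.027)
  n_ds <- 50L
  est <- matrix(0, n_ds, 3)
  for (k in seq_len(n_ds)) {
    set.seed(1000 + k)
    sdlog <- sqrt(log(1 + 0.1^2))
    syn <- linear_synthetic(truth,
                            noise_fac = function(n) rlnorm(n, 0, sdlog))
    est[k, ] <- fit_linear(syn$endpoints, syn$conditions)$model$scale
  }
  for (i in 1:3) {
    se <- sd(est[, i]) / sqrt(n_ds)
    expect_lt(abs(mean(est[, i]) - truth[i]), 2 * se)
  }
})

test_that("fit_coupled recovers a known activation model", {
  # 3 input-concentration levels per pair, zero noise
  truth <- coupled_wso(c(0.15, 0.12, 0.08), act_gain = 4, act_half = 1.2,
                       reporter_ref = 15)
  specs <- list()
  for (i in 1:3) for (x in c(1, 5, 10)) {
    inp <- c(0, 0, 0); inp[i] <- x
    specs <- c(specs, list(reaction_spec(inp, c(0.6, 0.6, 0.8),
                                         reporter_conc = 15,
                                         mode = "coupled",
                                         label = sprintf("p%dx%g", i, x))))
  }
  cs <- condition_set(specs, replicates = 1L)
  ep <- data.frame(
    condition = vapply(cs$specs, `[[`, "", "label"),
    replicate = 1L,
    endpoint_uM = vapply(cs$specs, function(sp) predict(truth, sp), 0.0))
  fit <- fit_coupled(ep, cs, seed = 4L)
  expect_lt(fit$rss, 1e-10)
  # scale and act_half share a common-factor degeneracy; the identifiable
  # quantities are act_gain and scale / act_half
  expect_equal(fit$model$act_gain, truth$act_gain, tolerance = 0.01)
  expect_equal(fit$model$scale / fit$model$act_half,
               truth$scale / truth$act_half, tolerance = 0.01)
  # with the activation constant constrained, everything is recovered
  fit_c <- fit_coupled(ep, cs, act_constraints = list(act_half = 1.2),
                       seed = 4L)
  expect_equal(fit_c$model$scale, truth$scale, tolerance = 0.01)
  expect_equal(fit_c$model$act_gain, truth$act_gain, tolerance = 0.01)
})

test_that("constrained coupled fit matches fit_linear in the linear regime", {
  truth <- c(0.02, 0.005, 0.0027)
  syn <- linear_synthetic(truth)  # direct-mode data, used as S << act_half
  cs <- wso_fixture("coupled_wso")  # same x*w designs? no: different weights
  # rebuild a coupled condition set with the same designs as the data
  specs <- lapply(wso_fixture("direct_wso")$specs, function(sp) {
    sp$mode <- "coupled"; sp$reporter_conc <- 15
    sp
  })
  cs <- condition_set(specs, replicates = 3L)
  K <- 1e3  # deep linear regime
  g <- 1e3
  fit <- fit_coupled(syn$endpoints, cs,
                     act_constraints = list(act_gain = g, act_half = K),
                     seed = 2L)
  lin <- fit_linear(syn$endpoints, wso_fixture("direct_wso"))
  # apparent slope scale * g / K recovers the linear scaling factors
  expect_equal(fit$model$scale * g / K, lin$model$scale, tolerance = 1e-3)
})

test_that("fit_coupled flags non-identifiable single-point designs", {
  ds <- zero_noise_dataset("coupled_wso", replicates = 2L)
  ep <- endpoints_table(ds)
  fit <- fit_coupled(ep, attr(ds, "conditions"), seed = 1L)
  expect_gt(length(fit$warnings), 0L)
  # zero data short-circuits to a zero model
  ep0 <- transform(ep, endpoint_uM = 0)
  fit0 <- fit_coupled(ep0, attr(ds, "conditions"))
  expect_equal(fit0$model$scale, c(0, 0, 0))
  expect_equal(fit0$rss, 0)
})

test_that("fit-then-predict reproduces a burden-free dataset exactly", {
  p0 <- default_params("direct")
  p0$mu_res <- 0
  ds <- zero_noise_dataset("direct_wso", replicates = 2L, params = p0)
  rep <- fit_predict_report(ds)
  expect_equal(nrow(rep), 8L)
  expect_setequal(rep$n_inputs, 0:3)
  expect_equal(rep$predicted_uM, rep$observed_mean_uM, tolerance = 1e-5)
})

test_that("the fitted linear model overpredicts under resource burden", {
  ds <- zero_noise_dataset("direct_wso", replicates = 2L)
  rep <- fit_predict_report(ds)
  multi <- rep[rep$n_inputs >= 2, ]
  expect_true(all(multi$predicted_uM >= multi$observed_mean_uM))
  # and strictly so: burden is active at the defaults
  expect_true(all(multi$predicted_uM > multi$observed_mean_uM * 1.001))
})

test_that("fit_predict_report requires the single-input block", {
  ds <- zero_noise_dataset("direct_wso", replicates = 2L)
  trimmed <- ds[!(ds$condition %in% c("in1", "in2", "in3")), ]
  attr(trimmed, "conditions") <- {
    cs <- attr(ds, "conditions")
    cs$specs <- cs$specs[!(names(cs$specs) %in% c("in1", "in2", "in3"))]
    cs
  }
  class(trimmed) <- class(ds)
  expect_error(fit_predict_report(trimmed), "single-input|8-combination")
})
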