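test_that("task-independent firing gives chance-level CPD", {
  set.seed(51)
  tr <- sim_trials(300, seed = 51)
  r <- spike_raster(lapply(1:300, function(i) sort(runif(rpois(1, 10), 0, 1000))),
                    window = c(0, 1000))
  br <- bin_rates(r, bin_width = 200, step = 100)
  fit <- unit_decision_model(br, tr)
  chance <- chance_cpd(300, 5)
  expect_lt(mean(fit$cpd), 4 * chance)
})

test_that("a rate that equals the value difference yields CPD of 1", {
  tr <- sim_trials(100, seed = 52)
  dv <- tr$value_left - tr$value_right
  R <- matrix(rnorm(100 * 3, 10, 1), 100, 3)
  R[, 2] <- dv  # one bin carries the regressor exactly
  br <- structure(list(rates = R, bin_centers_ms = c(100, 300, 500),
                       bin_width_ms = 200, unit_id = 1, region = "DLPFC",
                       electrode_id = 1), class = "binned_rates")
  fit <- unit_decision_model(br, tr)
  expect_equal(unname(fit$cpd[2, "value_diff"]), 1, tolerance = 1e-9)
})

test_that("generated units transition from value-difference to choice coding", {
  tr <- sim_trials(400, seed = 53)
  m <- spike_model(baseline_hz = 12, early_gain = 6, late_gain = 7,
                   cv_gain = 0, latent_gain = 0)
  units <- sim_spikes(tr, m, n_units = 8, window = c(-400, 1200), seed = 53)
  peaks <- t(vapply(units, function(u) {
    fit <- unit_decision_model(bin_rates(u, 200, 50), tr)
    sel <- fit$bin_centers_ms >= 0 & fit$bin_centers_ms <= 1000
    c(dv = fit$bin_centers_ms[sel][which.max(fit$cpd[sel, "value_diff"])],
      ch = fit$bin_centers_ms[sel][which.max(fit$cpd[sel, "choice"])])
  }, c(dv = 1, ch = 1)))
  expect_lt(mean(peaks[, "dv"]), mean(peaks[, "ch"]))

  # early value-difference selectivity predicts late choice selectivity
  zz <- t(vapply(units, function(u) {
    fit <- unit_decision_model(bin_rates(u, 200, 50), tr)
    j300 <- which.min(abs(fit$bin_centers_ms - 300))
    j700 <- which.min(abs(fit$bin_centers_ms - 700))
    c(fit$z[j300, "value_diff"], fit$z[j700, "choice"])
  }, c(a = 1, b = 1)))
  expect_gt(cor(zz[, 1], zz[, 2]), 0)
})

test_that("degenerate single-type sessions drop the empty constant", {
  tr <- sim_trials(100, seed = 54)
  tr$trial_type <- "effort"
  r <- poisson_raster(100, 10, window = c(0, 1000), seed = 54)
  br <- bin_rates(r, 200, 200)
  expect_warning(fit <- unit_decision_model(br, tr), "const_delay")
  expect_false("const_delay" %in% fit$design)
})

test_that("LFP value regression is calibrated on value-free data", {
  set.seed(55)
  tr <- sim_trials(400, seed = 55)
  tms <- time_grid(c(-200, 1000), 100)
  arr <- lfp_array(matrix(rnorm(400 * length(tms)), 400), tms, 100)
  out <- lfp_value_regression(arr, tr)
  frac <- mean(abs(out$z_chosen) > 2)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.12)
})

test_that("amplitude-coded value sum gives same-sign early coefficients", {
  tr <- sim_trials(500, seed = 56)
  m <- erp_model(amp_gain = 0.3, sigma_amp = 0.05, latency_gain = 0,
                 latency_error = 0, sigma_shared = 0, sigma_local = 0,
                 sigma_noise = 0.1)
  lfp <- sim_lfp(tr, m, n_electrodes_per_region = 3, seed = 56)
  out <- lfp_value_regression(lfp, tr)
  # at the early template peak the response scales with value sum, so chosen
  # and unchosen carry the same sign
  j <- which.min(abs(out$time_ms - 150))
  expect_gt(out$mean_z["chosen", j] * out$mean_z["unchosen", j], 0)
})

test_that("latency-coded value peaks where the ERP ramps, not where it peaks", {
  tr <- sim_trials(500, seed = 57)
  m <- erp_model(amp_gain = 0, sigma_amp = 0, latency_gain = 12,
                 latency_error = 0, sigma_shared = 4, sigma_local = 0,
                 sigma_noise = 0.1)
  lfp <- sim_lfp(tr, m, n_electrodes_per_region = 2, seed = 57)
  out <- lfp_value_regression(lfp, tr)
  erp <- colMeans(lfp[[1]]$data)
  der <- erp_derivative(erp, 100)
  absz <- abs(out$mean_z["chosen", ])
  # |Z| profile tracks |derivative| better than |ERP|
  expect_gt(cor(absz, abs(der)), cor(absz, abs(erp)))
})

test_that("PC-weight regressions recover generator signs and RT effects", {
  # null: weights unrelated to the task
  set.seed(58)
  tr <- sim_trials(300, seed = 58)
  out_null <- pc_weight_regression(rnorm(300), tr)
  expect_true(all(abs(out_null$z[-1]) < 4))

  # generator defaults: higher chosen value and errors -> earlier waveform,
  # so both coefficients on earliness-oriented latency weights are positive
  tr2 <- sim_trials(600, seed = 59)
  lfp <- sim_lfp(tr2, erp_model(), n_electrodes_per_region = 2, seed = 59)
  st <- stack_trials(lfp)
  fit <- decompose_lfp(st, exclude = rep(FALSE, nrow(st$X)))
  w <- latency_weights(fit)
  tr_stacked <- rbind(tr2, tr2)
  wr <- pc_weight_regression(w, tr_stacked)
  expect_gt(wr$estimate[wr$regressor == "chosen_value"], 0)
  expect_gt(wr$z[wr$regressor == "chosen_value"], 2)
  expect_gt(wr$estimate[wr$regressor == "error"], 0)

  # MEG-style data: RT negatively predicts earliness beyond task variables
  meg <- sim_meg_subjects(6, 150, seed = 60)
  signs <- align_subject_signs(meg$lfp)
  aligned <- lapply(seq_along(meg$lfp), function(s) {
    a <- meg$lfp[[s]]
    a$data <- signs[s] * a$data
    a
  })
  expect_lt(cor(meg$trials$rt_ms, meg$trials$chosen_value), 0)
  stm <- stack_trials(aligned)
  fitm <- decompose_lfp(stm, exclude = rep(FALSE, nrow(stm$X)))
  wm <- latency_weights(fitm)
  wrm <- pc_weight_regression(wm, meg$trials, include_rt = TRUE)
  expect_lt(wrm$estimate[wrm$regressor == "rt"], 0)
  expect_lt(wrm$z[wrm$regressor == "rt"], -2)
})
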