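# Shared construction: a session where spikes and LFP ride the same latent.
coupled_session <- function(n_trials = 400, n_units = 6, seed = 61,
                            latent_gain = 5, cv_gain = 0, mediation = 0) {
  tr <- sim_trials(n_trials, seed = seed)
  lfp <- sim_lfp(tr, erp_model(), n_electrodes_per_region = 2, seed = seed)
  gt <- attr(lfp, "truth")
  tau1 <- gt$tau[gt$electrode_id == 1]
  sm <- spike_model(baseline_hz = 12, early_gain = 4, late_gain = 5,
                    cv_gain = cv_gain, latent_gain = latent_gain,
                    mediation = mediation)
  units <- sim_spikes(tr, sm, latents = tau1, n_units = n_units,
                      window = c(-500, 1200), seed = seed + 1)
  st <- stack_trials(lfp)
  fit <- decompose_lfp(st, exclude = rep(FALSE, nrow(st$X)))
  w_lat <- latency_weights(fit)
  # rows of electrode 1 (row order: electrode 1 trials then electrode 2)
  e1 <- fit$row_index$electrode_id == 1
  list(trials = tr, units = units, fit = fit,
       w1 = w_lat[e1], tau1 = tau1,
       scores = coef(fit), e1 = e1)
}

test_that("PC coupling appears when spikes and LFP share a latent", {
  cs <- coupled_session()
  br <- bin_rates(cs$units[[1]], 200, 100)
  aug <- augmented_unit_model(br, cs$trials, cs$w1)
  mid <- aug$bin_centers_ms >= 300 & aug$bin_centers_ms <= 700
  chance <- chance_cpd(400, length(aug$design))

  # permuted weights break the coupling
  set.seed(62)
  aug_perm <- augmented_unit_model(br, cs$trials, sample(cs$w1))
  expect_lt(mean(aug_perm$cpd), 4 * chance)
  expect_gt(mean(aug$cpd[mid, ]), mean(aug_perm$cpd[mid, ]) + 0.01)
  # coupling peaks mid-trial, where the latent kernel lives
  expect_true(aug$bin_centers_ms[which.max(aug$cpd)] >= 200 &&
                aug$bin_centers_ms[which.max(aug$cpd)] <= 800)

  # the full covariate set tells the same story as the reduced one
  aug_full <- augmented_unit_model(br, cs$trials, cs$w1, set = "full19")
  expect_equal(length(aug_full$design), 20)  # 19 covariates + the PC term
  expect_gt(cor(aug$cpd[, 1], aug_full$cpd[, 1]), 0.9)
  expect_lt(abs(mean(aug$cpd[mid, ]) - mean(aug_full$cpd[mid, ])),
            0.5 * mean(aug$cpd[mid, ]))
})

test_that("latent-free task coupling produces no spurious PC coupling", {
  tr <- sim_trials(300, seed = 63)
  sm <- spike_model(baseline_hz = 12, early_gain = 5, late_gain = 5,
                    cv_gain = 4, latent_gain = 0, mediation = 0)
  units <- sim_spikes(tr, sm, n_units = 1, window = c(-500, 1200),
                      seed = 64)
  br <- bin_rates(units[[1]], 200, 100)
  w <- rnorm(300)  # weights unrelated to anything
  aug <- augmented_unit_model(br, tr, w)
  set.seed(65)
  null_cpd <- vapply(1:40, function(i)
    mean(augmented_unit_model(br, tr, sample(w))$cpd), 1)
  p <- (sum(null_cpd >= mean(aug$cpd)) + 1) / 41
  expect_gt(p, 0.05)
})

test_that("CPD reduction isolates latent-mediated chosen-value coding", {
  cs <- coupled_session(latent_gain = 0, cv_gain = 6, mediation = 1,
                        seed = 66)
  ctl_idx <- noise_components(cs$fit)
  pcs <- cs$scores[cs$e1, 1:2]
  ctl <- cs$scores[cs$e1, ctl_idx]
  red <- cpd_reduction(bin_rates(cs$units[[1]], 200, 100), cs$trials,
                       pcs, ctl)
  mid <- red$bin_centers_ms >= 300 & red$bin_centers_ms <= 700
  expect_gt(mean(red$delta_cpd[mid, "chosen_value"]), 0.01)
  expect_lt(mean(abs(red$delta_cpd[mid, "value_diff"])),
            mean(red$delta_cpd[mid, "chosen_value"]) / 2)
  expect_lt(mean(abs(red$delta_cpd[mid, "choice"])),
            mean(red$delta_cpd[mid, "chosen_value"]) / 2)
  # the reduction can never exceed the control-model CPD
  expect_true(all(red$delta_cpd <= red$cpd_control_model + 1e-12))

  # independent weights: no systematic reduction anywhere
  set.seed(67)
  red0 <- cpd_reduction(bin_rates(cs$units[[2]], 200, 100), cs$trials,
                        matrix(rnorm(800), 400), matrix(rnorm(800), 400))
  expect_lt(max(abs(colMeans(red0$delta_cpd))), 0.01)
})

test_that("value-preserving shuffle keeps the value correlation only", {
  cs <- coupled_session(seed = 68)
  w <- cs$w1
  ws <- shuffled_pc_control(w, cs$trials, seed = 68)
  r_pre <- cor(w, cs$trials$chosen_value)
  r_post <- cor(ws, cs$trials$chosen_value)
  expect_lt(abs(r_pre - r_post), 0.12)
  # trial-specific coupling to the latent is destroyed
  expect_lt(abs(cor(ws, cs$tau1)), abs(cor(w, cs$tau1)) / 2)
  # singleton strata stay in place
  trs <- tiny_trials(4)
  trs$chosen_value <- c(3, 2, 1, 0)
  expect_identical(shuffled_pc_control(1:4, trs, seed = 1), 1:4)
})

test_that("local-vs-distal attribution finds region-private latents", {
  # spikes couple to the locally-private part of the latent
  tr <- sim_trials(400, seed = 69)
  m <- erp_model(sigma_shared = 8, sigma_local = 12, latency_error = 0)
  lfp <- sim_lfp(tr, m, n_electrodes_per_region = 2,
                 regions = c("DLPFC", "ACC"), seed = 69)
  gt <- attr(lfp, "truth")
  st <- stack_trials(lfp)
  fit <- decompose_lfp(st, exclude = rep(FALSE, nrow(st$X)))
  w <- latency_weights(fit)
  lat <- attr(w, "component")
  amp <- setdiff(1:2, lat)
  sc <- coef(fit)
  rows_of <- function(e) which(fit$row_index$electrode_id == e)
  local_pcs <- sc[rows_of(1), c(amp, lat)]
  distal_pcs <- sc[rows_of(3), c(amp, lat)]
  ctl <- sc[rows_of(1), noise_components(fit)]

  tau_local <- gt$tau[gt$electrode_id == 1]
  sm <- spike_model(baseline_hz = 12, early_gain = 3, late_gain = 3,
                    cv_gain = 0, latent_gain = 6)
  units <- sim_spikes(tr, sm, latents = tau_local, n_units = 1,
                      window = c(-500, 1200), seed = 70)
  br <- bin_rates(units[[1]], 200, 100)
  lvd <- local_vs_distal(br, tr, local_pcs, distal_pcs, ctl)
  mid <- lvd$bin_centers_ms >= 300 & lvd$bin_centers_ms <= 700
  # region-private latents drive the spikes, so the locally-orthogonalised
  # weights explain away more chosen-value coding than the distal ones
  expect_gt(mean(lvd$ddelta_cpd[mid, "chosen_value"]), 0.005)

  # identical local and distal weights: exact symmetry, zero difference
  lvd0 <- local_vs_distal(br, tr, local_pcs, local_pcs, ctl)
  expect_lt(max(abs(lvd0$ddelta_cpd)), 1e-10)
  # antisymmetry under swapping the two sources
  lvd_swap <- local_vs_distal(br, tr, distal_pcs, local_pcs, ctl)
  expect_equal(lvd_swap$ddelta_cpd, -lvd$ddelta_cpd, tolerance = 1e-10)
})

test_that("cross-region model recovers trial-type-specific coupling", {
  set.seed(71)
  tr <- sim_trials(400, seed = 71)
  acc_w <- rnorm(400)
  ofc_w <- rnorm(400)
  eff <- tr$trial_type == "effort"
  tms <- seq(-400, 1100, by = 100)
  k_mid <- exp(-0.5 * ((tms - 500) / 150)^2)
  make_units <- function(gain_acc_eff, gain_ofc_del, n_units = 5) {
    lapply(seq_len(n_units), function(u) {
      R <- matrix(NA_real_, 400, length(tms))
      for (i in 1:400) {
        rate <- 12 + gain_acc_eff * k_mid * acc_w[i] * eff[i] +
          gain_ofc_del * k_mid * ofc_w[i] * (!eff[i])
        R[i, ] <- rpois(length(tms), pmax(rate, 0) * 0.2) / 0.2
      }
      structure(list(rates = R, bin_centers_ms = tms, bin_width_ms = 200,
                     unit_id = u, region = "DLPFC", electrode_id = 1),
                class = "binned_rates")
    })
  }

  # effort-only ACC coupling: ACC effort-delay difference positive, OFC ~ 0
  units <- make_units(5, 0)
  mid <- tms >= 300 & tms <= 700
  diffs <- t(vapply(units, function(br) {
    cr <- cross_region_model(br, tr, ofc_w, acc_w,
                             source_names = c("OFC", "ACC"))
    colMeans(cr$effort_minus_delay[mid, ])
  }, c(OFC = 1, ACC = 1)))
  expect_gt(mean(diffs[, "ACC"]), 0.01)
  expect_lt(abs(mean(diffs[, "OFC"])), 0.01)

  # delay-only OFC coupling: OFC difference negative
  units2 <- make_units(0, 5)
  diffs2 <- t(vapply(units2, function(br) {
    cr <- cross_region_model(br, tr, ofc_w, acc_w,
                             source_names = c("OFC", "ACC"))
    colMeans(cr$effort_minus_delay[mid, ])
  }, c(OFC = 1, ACC = 1)))
  expect_lt(mean(diffs2[, "OFC"]), -0.01)

  # fully independent rates: everything at chance
  units3 <- make_units(0, 0, n_units = 3)
  cr3 <- cross_region_model(units3[[1]], tr, ofc_w, acc_w)
  expect_lt(mean(cr3$cpd), 4 * chance_cpd(400, 6))
  expect_error(cross_region_model(units3[[1]],
                                  transform(tr, trial_type = "effort"),
                                  ofc_w, acc_w), "both trial types")
})

test_that("median split is deterministic with the documented tie rule", {
  s <- c(5, 1, 3, 3, 2, 4)
  ms <- median_split(s)
  expect_equal(sort(c(ms$low, ms$high)), 1:6)
  expect_equal(length(ms$low), 3)
  expect_true(2 %in% ms$low && 5 %in% ms$low)
  expect_true(1 %in% ms$high)
  # ties: first-seen goes low
  expect_true(3 %in% ms$low && 4 %in% ms$high)

  ms124 <- median_split(rnorm(124))
  expect_equal(c(length(ms124$low), length(ms124$high)), c(62L, 62L))
  # all-equal selectivities: stable order, same sizes
  msq <- median_split(rep(1, 124))
  expect_equal(msq$low, 1:62)
  # odd n: lower half takes the extra unit
  ms7 <- median_split(7:1)
  expect_equal(length(ms7$low), 4)
})

test_that("weight correlations are larger within than between regions", {
  tr <- sim_trials(300, seed = 72)
  m <- erp_model(sigma_shared = 12, sigma_local = 6, sigma_noise = 0.1)
  lfp <- sim_lfp(tr, m, n_electrodes_per_region = 3,
                 regions = c("DLPFC", "OFC"), seed = 72)
  st <- stack_trials(lfp)
  fit <- decompose_lfp(st, exclude = rep(FALSE, nrow(st$X)))
  w <- latency_weights(fit)
  regions <- vapply(1:6, function(e)
    attr(lfp, "truth")$region[attr(lfp, "truth")$electrode_id == e][1], "")
  weights <- lapply(1:6, function(e) w[fit$row_index$electrode_id == e])
  cc <- pc_weight_cross_correlation(weights, regions)
  expect_gt(cc$medians["within"], cc$medians["between"])
  expect_gt(cc$medians["between"], 0)  # value-driven part is global

  # independent weights centre at zero
  set.seed(73)
  cc0 <- pc_weight_cross_correlation(
    lapply(1:6, function(e) rnorm(300)), regions)
  expect_lt(abs(median(cc0$pairs$r)), 0.1)
  # an electrode paired with itself correlates perfectly
  cc1 <- pc_weight_cross_correlation(list(weights[[1]], weights[[1]]),
                                     c("A", "A"))
  expect_equal(cc1$pairs$r, 1)
})
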