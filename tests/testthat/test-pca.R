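test_that("stacking has the documented dimensions and a faithful row index", {
  a1 <- template_array(3)
  st <- stack_trials(list(a1))
  expect_equal(dim(st$X), c(3, 120))

  arrays <- list()
  for (s in 1:2) for (e in 1:2) {
    a <- template_array(10, tau = rnorm(10, 0, 5))
    a$session_id <- s
    a$electrode_id <- e
    arrays[[length(arrays) + 1]] <- a
  }
  st2 <- stack_trials(arrays)
  expect_equal(nrow(st2$X), 40)  # nElectrodes * nTrials
  expect_equal(nrow(st2$row_index), 40)
  # round trip: each row is recoverable from its source array
  for (r in c(1, 17, 40)) {
    ri <- st2$row_index[r, ]
    src <- Filter(function(a) a$session_id == ri$session_id &&
                    a$electrode_id == ri$electrode_id, arrays)[[1]]
    k <- src$time_ms >= -200 & src$time_ms < 1000
    expect_equal(unname(st2$X[r, ]), unname(src$data[ri$trial_id, k]))
  }
  expect_error(stack_trials(list(a1, lfp_array(matrix(0, 2, 60),
                                               time_grid(c(-200, 1000), 50),
                                               50))),
               "sampling rate")
})

test_that("artifact exclusion flags exactly the high-variability rows", {
  set.seed(21)
  X <- matrix(rnorm(501 * 120, 0, 0.1), 501)
  X[77, ] <- rnorm(120, 0, 1)  # one row with 10x the noise SD
  mask <- artifact_mask(X)
  expect_equal(which(mask), 77L)
  # zero index spread: nothing excluded (strict inequality at the threshold)
  expect_false(any(artifact_mask(matrix(rep(rnorm(60), 5), 5, byrow = TRUE))))
  expect_error(artifact_mask(X[1, , drop = FALSE]), "2 rows")
})

test_that("rank-1 amplitude variation loads on a single component", {
  set.seed(22)
  amp <- rnorm(100, 0, 0.3)
  arr <- template_array(100, amp = amp)
  st <- stack_trials(arr)
  fit <- decompose_lfp(st, k = 5, exclude = rep(FALSE, 100),
                       sign_anchors = list())
  expect_gt(fit$explained_variance_fraction[1], 0.99)
  expect_equal(abs(cor(fit$U[, 1], amp)), 1, tolerance = 1e-6)
})

test_that("small latency jitter loads on a derivative-shaped component", {
  set.seed(23)
  tau <- rnorm(100, 0, 2)  # small shifts: first-order regime
  arr <- template_array(100, tau = tau)
  st <- stack_trials(arr)
  fit <- decompose_lfp(st, k = 5, exclude = rep(FALSE, 100),
                       sign_anchors = list())
  r <- max(abs(cor(fit$U[, 1], tau)), abs(cor(fit$U[, 2], tau)))
  expect_gt(r, 0.99)
})

test_that("identical rows decompose to zero weights", {
  arr <- template_array(10)
  st <- stack_trials(arr)
  fit <- decompose_lfp(st, k = 3, exclude = rep(FALSE, 10),
                       sign_anchors = list())
  expect_lt(max(abs(coef(fit))), 1e-8)
  # but anchoring a zero-variance component is an error
  expect_error(decompose_lfp(st, k = 3, exclude = rep(FALSE, 10)),
               "zero singular value")
})

test_that("SVD reconstruction reproduces the retained demeaned rows", {
  tr <- sim_trials(80, seed = 24)
  lfp <- sim_lfp(tr, erp_model(), n_electrodes_per_region = 2, seed = 24)
  st <- stack_trials(lfp)
  fit <- decompose_lfp(st)
  keep <- !fit$excluded_rows
  Xd <- sweep(st$X[keep, ], 2, fit$mean_timecourse)
  Xhat <- fit$U %*% diag(fit$d) %*% t(fit$V)
  expect_lt(max(abs(Xd - Xhat)) / max(abs(Xd)), 1e-8)
  # weights come back for every retained row (one per trial per electrode)
  expect_equal(nrow(fit$U), sum(keep))
  # explained variance ordered and summing to at most 1
  ev <- fit$explained_variance_fraction
  expect_true(all(diff(ev) <= 1e-12))
  expect_lte(sum(ev), 1 + 1e-9)
})

test_that("sign anchors impose the required signs and record snapping", {
  tr <- sim_trials(60, seed = 25)
  lfp <- sim_lfp(tr, erp_model(), n_electrodes_per_region = 1, seed = 25)
  st <- stack_trials(lfp)
  fit <- decompose_lfp(st, k = 4)
  j190 <- which.min(abs(st$time_ms - 190))
  j530 <- which.min(abs(st$time_ms - 530))
  expect_gte(fit$V[j190, 1], 0)
  expect_lte(fit$V[j530, 2], 0)
  # off-grid anchor time snaps to the nearest sample and is recorded
  fit2 <- decompose_lfp(st, k = 2, sign_anchors = list(c(1, 1, 193)))
  expect_equal(length(fit2$snapped_anchors), 1)
  expect_equal(unname(fit2$snapped_anchors[[1]]["used"]), 190)
})

test_that("reconstruction sweeps act as amplitude and latency knobs", {
  set.seed(26)
  arr <- template_array(300, tau = rnorm(300, 0, 8),
                        amp = rnorm(300, 0, 0.25), noise_sd = 0.05)
  st <- stack_trials(arr)
  fit <- decompose_lfp(st, exclude = rep(FALSE, 300))
  expect_equal(reconstruct_erp(fit, c(`1` = 0)), fit$mean_timecourse)

  lat <- latency_component(fit)$component
  amp <- setdiff(1:2, lat)
  late <- fit$time_ms >= 300 & fit$time_ms <= 900
  # latency of the late wave as the half-amplitude leading-edge crossing
  # (scale-invariant, robust to the broad trough of this template)
  latency_of <- function(w) {
    tt <- fit$time_ms[late]
    ww <- w[late]
    half <- min(ww) / 2
    j <- which(ww < half)[1]
    tt[j - 1] + (tt[j] - tt[j - 1]) *
      (half - ww[j - 1]) / (ww[j] - ww[j - 1])
  }
  sweep_vals <- seq(-2, 2, length.out = 7) * fit$d[lat] / sqrt(nrow(fit$U))
  lat_t <- vapply(sweep_vals, function(dl)
    latency_of(reconstruct_erp(fit, stats::setNames(dl, lat))), 1)
  expect_true(all(diff(lat_t) <= 0) || all(diff(lat_t) >= 0))
  expect_gt(max(lat_t) - min(lat_t), 15)  # the knob actually moves latency

  sweep_amp <- seq(-2, 2, length.out = 7) * fit$d[amp] / sqrt(nrow(fit$U))
  depth <- vapply(sweep_amp, function(da)
    min(reconstruct_erp(fit, stats::setNames(da, amp))[late]), 1)
  expect_true(all(diff(depth) <= 0) || all(diff(depth) >= 0))
  amp_t <- vapply(sweep_amp, function(da)
    latency_of(reconstruct_erp(fit, stats::setNames(da, amp))), 1)
  expect_lte(max(amp_t) - min(amp_t), 10 + 1e-9)  # within one sample
})

test_that("subject sign alignment recovers planted flips up to global sign", {
  set.seed(27)
  base <- lapply(1:6, function(s) template_array(30, tau = rnorm(30, 0, 8),
                                                noise_sd = 0.05))
  # no flips planted: all +1
  expect_equal(align_subject_signs(base), rep(1L, 6))
  # plant flips on half the subjects
  planted <- c(1, -1, 1, -1, 1, -1)
  flipped <- lapply(seq_along(base), function(s) {
    a <- base[[s]]
    a$data <- planted[s] * a$data
    a
  })
  got <- align_subject_signs(flipped)
  expect_true(all(got * planted == 1) || all(got * planted == -1))
  # invariant to subject ordering
  perm <- c(4, 2, 6, 1, 3, 5)
  got_perm <- align_subject_signs(flipped[perm])
  expect_true(all(got_perm == got[perm]) || all(got_perm == -got[perm]))
  expect_error(align_subject_signs(base[1]), "2 subjects")
})

test_that("noise-component fallback warns when the spectrum is short", {
  tr <- sim_trials(40, seed = 28)
  st <- stack_trials(sim_lfp(tr, erp_model(),
                             n_electrodes_per_region = 1, seed = 28))
  fit <- decompose_lfp(st, k = 10, exclude = rep(FALSE, 40))
  expect_warning(nc <- noise_components(fit), "last two")
  expect_equal(nc, c(9L, 10L))
  tr2 <- sim_trials(150, seed = 29)
  st2 <- stack_trials(sim_lfp(tr2, erp_model(),
                              n_electrodes_per_region = 1, seed = 29))
  fit3 <- decompose_lfp(st2, exclude = rep(FALSE, 150))
  expect_silent(nc2 <- noise_components(fit3))
  expect_equal(nc2, c(101L, 102L))
})
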