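#' Stack single-trial waveforms across electrodes and sessions
#'
#' Forms the row-stacked cross-trial matrix X whose rows are single trials on
#' single electrodes and whose columns are timepoints, so the dimensions are
#' `[nRecordedElectrodes * nTrials] x nTimepoints`. Rows are ordered
#' deterministically by (session, electrode, trial), and a complete row index
#' is kept so every row maps back to its recording.
#'
#' @param arrays list of [lfp_array()] sharing sampling rate and covering
#'   `window`.
#' @param window analysis window `c(t0, t1)` in ms (half-open); default
#'   -200..+1000 ms around choice onset.
#' @return object of class `stacked_lfp`: `X` (rows x time), `row_index`
#'   (data.frame: session_id, electrode_id, trial_id, subject_id), `time_ms`,
#'   `fs_hz`, `window`.
#' @export
stack_trials <- function(arrays, window = c(-200, 1000)) {
  if (inherits(arrays, "lfp_array")) arrays <- list(arrays)
  fs <- vapply(arrays, function(a) a$fs_hz, 1)
  if (diff(range(fs)) > 1e-9) stop("all arrays must share the sampling rate")
  ord <- order(vapply(arrays, function(a) a$session_id, 1L),
               vapply(arrays, function(a) as.integer(a$electrode_id), 1L))
  arrays <- arrays[ord]

  sel_time <- function(a) {
    k <- a$time_ms >= window[1] - 1e-9 & a$time_ms < window[2] - 1e-9
    if (!any(k)) stop("array does not cover the requested window")
    k
  }
  k0 <- sel_time(arrays[[1]])
  tms <- arrays[[1]]$time_ms[k0]
  Xs <- lapply(arrays, function(a) {
    k <- sel_time(a)
    if (sum(k) != length(tms)) stop("arrays do not cover the window equally")
    a$data[, k, drop = FALSE]
  })
  idx <- do.call(rbind, lapply(arrays, function(a)
    data.frame(session_id = a$session_id,
               electrode_id = as.integer(a$electrode_id),
               trial_id = seq_len(nrow(a$data)),
               subject_id = a$subject_id)))
  structure(list(X = do.call(rbind, Xs), row_index = idx, time_ms = tms,
                 fs_hz = fs[1], window = window),
            class = "stacked_lfp")
}

#' @export
print.stacked_lfp <- function(x, ...) {
  cat(sprintf("<stacked_lfp> %d rows (trials x electrodes) x %d timepoints, [%g, %g) ms\n",
              nrow(x$X), ncol(x$X), x$window[1], x$window[2]))
  invisible(x)
}

#' Flag artifact rows of a stacked matrix
#'
#' Within-trial variability is indexed by the square root of the standard
#' deviation of the waveform across time; rows whose index lies strictly
#' more than `z_thresh` standard deviations above the mean index are flagged.
#' The default 2.32 is the Gaussian 99th-percentile quantile truncated to two
#' decimals.
#'
#' @param X a `stacked_lfp` or a plain rows-by-time matrix (>= 2 rows).
#' @param z_thresh exclusion threshold in SD units of the variability index.
#' @return logical vector, `TRUE` for excluded rows.
#' @export
artifact_mask <- function(X, z_thresh = 2.32) {
  if (inherits(X, "stacked_lfp")) X <- X$X
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows to estimate index spread")
  idx <- sqrt(apply(X, 1, sd))
  s <- sd(idx)
  if (!is.finite(s) || s == 0) return(rep(FALSE, nrow(X)))
  idx > mean(idx) + z_thresh * s
}

#' Decompose stacked single-trial waveforms into temporal components
#'
#' Removes the mean timecourse (per-timepoint mean over retained rows, i.e.
#' the grand-average evoked response), runs an SVD of the demeaned retained
#' rows, and applies sign conventions: each anchored component is flipped, if
#' needed, so its temporal shape has the required sign at the anchor time
#' (nearest sample; snaps are recorded). With the defaults, component 1 is
#' positive 190 ms and component 2 negative 530 ms after onset, which makes
#' the amplitude/latency interpretation of the weights consistent across
#' datasets.
#'
#' @param stacked a [stack_trials()] object.
#' @param k number of components to retain (default: all).
#' @param sign_anchors list of `c(component, sign, time_ms)` triples.
#' @param exclude logical row mask (default [artifact_mask()] at 2.32 SD).
#' @param demean `"global"` (per-timepoint mean over all retained rows) or
#'   `"electrode"` (per-electrode mean timecourse).
#' @return object of class `lfp_pca`: `V` (time x k, orthonormal), `U` (rows
#'   x k, orthonormal weights), `d` (singular values),
#'   `explained_variance_fraction`, `sign_flips`, `excluded_rows`,
#'   `mean_timecourse`, `row_index` (retained rows), `time_ms`.
#' @examples
#' tr <- sim_trials(60, seed = 2)
#' st <- stack_trials(sim_lfp(tr, seed = 2))
#' fit <- decompose_lfp(st, k = 5)
#' fit
#' @export
decompose_lfp <- function(stacked, k = NULL,
                          sign_anchors = list(c(1, +1, 190), c(2, -1, 530)),
                          exclude = NULL, demean = c("global", "electrode")) {
  stopifnot(inherits(stacked, "stacked_lfp"))
  demean <- match.arg(demean)
  X <- stacked$X
  if (is.null(exclude)) exclude <- artifact_mask(X)
  stopifnot(length(exclude) == nrow(X))
  keep <- !exclude
  Xr <- X[keep, , drop = FALSE]
  idx <- stacked$row_index[keep, , drop = FALSE]

  if (demean == "global") {
    mu <- colMeans(Xr)
    Xd <- sweep(Xr, 2, mu)
  } else {
    key <- interaction(idx$session_id, idx$electrode_id, drop = TRUE)
    Xd <- Xr
    for (g in levels(key)) {
      rows <- key == g
      Xd[rows, ] <- sweep(Xr[rows, , drop = FALSE], 2,
                          colMeans(Xr[rows, , drop = FALSE]))
    }
    mu <- colMeans(Xr)
  }

  sv <- svd(Xd)
  kmax <- length(sv$d)
  if (is.null(k)) k <- kmax
  if (k > kmax) stop("k exceeds min(rows, timepoints)")
  evar_all <- sv$d^2 / sum(sv$d^2)

  V <- sv$v[, seq_len(k), drop = FALSE]
  U <- sv$u[, seq_len(k), drop = FALSE]
  d <- sv$d[seq_len(k)]

  flips <- integer(0)
  snapped <- list()
  for (an in sign_anchors) {
    comp <- an[1]; want <- an[2]; at <- an[3]
    if (comp > k) next
    j <- which.min(abs(stacked$time_ms - at))
    if (abs(stacked$time_ms[j] - at) > 1e-9)
      snapped[[length(snapped) + 1]] <-
        c(component = comp, requested = at, used = stacked$time_ms[j])
    if (d[comp] <= max(d) * 1e-12)
      stop("zero singular value at anchored component ", comp)
    if (sign(V[j, comp]) != 0 && sign(V[j, comp]) != sign(want)) {
      V[, comp] <- -V[, comp]
      U[, comp] <- -U[, comp]
      flips <- c(flips, comp)
    }
  }

  structure(list(V = V, U = U, d = d,
                 explained_variance_fraction = evar_all[seq_len(k)],
                 sign_flips = flips, snapped_anchors = snapped,
                 excluded_rows = exclude, mean_timecourse = mu,
                 row_index = idx, time_ms = stacked$time_ms, k = k,
                 demean = demean),
            class = "lfp_pca")
}

#' @export
print.lfp_pca <- function(x, ...) {
  cat(sprintf("<lfp_pca> %d retained rows (%d excluded), %d components\n",
              nrow(x$U), sum(x$excluded_rows), x$k))
  ev <- x$explained_variance_fraction
  cat(sprintf("  explained variance: %s%s\n",
              paste(sprintf("PC%d %.1f%%", seq_len(min(3, x$k)),
                            100 * ev[seq_len(min(3, x$k))]), collapse = ", "),
              if (x$k > 3) ", ..." else ""))
  if (length(x$sign_flips))
    cat("  sign-flipped components:", paste(x$sign_flips, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.lfp_pca <- function(object, ...) {
  print(object)
  cat(sprintf("  reconstruction uses U diag(d) V' + mean timecourse\n"))
  invisible(object)
}

#' Single-trial component weights (scores)
#'
#' Returns `U %*% diag(d)`: the projection of each retained demeaned row onto
#' the temporal components, one row per trial per electrode.
#'
#' @param object an `lfp_pca` fit.
#' @param ... unused.
#' @export
coef.lfp_pca <- function(object, ...) {
  sweep(object$U, 2, object$d, `*`)
}

#' @export
plot.lfp_pca <- function(x, components = 1:2, ...) {
  matplot(x$time_ms, x$V[, components, drop = FALSE], type = "l", lty = 1,
          xlab = "time (ms)", ylab = "component amplitude (a.u.)", ...)
  abline(h = 0, col = "grey")
  legend("topright", legend = paste0("PC", components), lty = 1,
         col = seq_along(components), bty = "n")
  invisible(x)
}

#' Reconstruct a waveform from the mean ERP plus component deltas
#'
#' `mean_timecourse + sum_j delta_j * V[, j]`: sweeping the latency
#' component's delta moves the late peak in time; sweeping the amplitude
#' component's delta scales it.
#'
#' @param fit an `lfp_pca`.
#' @param deltas named numeric vector; names are component indices.
#' @return waveform on the fit's time axis.
#' @export
reconstruct_erp <- function(fit, deltas = c(`1` = 0)) {
  stopifnot(inherits(fit, "lfp_pca"))
  comps <- as.integer(names(deltas))
  if (any(is.na(comps)) || any(comps < 1) || any(comps > fit$k))
    stop("deltas must be named by component indices within 1..k")
  w <- fit$mean_timecourse
  for (i in seq_along(comps)) w <- w + deltas[i] * fit$V[, comps[i]]
  w
}

#' Identify the latency-like component
#'
#' Finds the component whose single-trial weights index waveform latency,
#' without hard-coding its position -- necessary because different dynamical
#' regimes put latency variance in different components (transient evoked
#' recordings typically in component 2, ramp-to-attractor dynamics in
#' component 1). Two LFP-intrinsic criteria are available:
#'
#' * `"derivative"` (default): a latency shift is, to first order, admixture
#'   of the waveform's temporal derivative, so the latency component is the
#'   one whose temporal shape correlates most strongly (in absolute value)
#'   with the smoothed derivative of the mean ERP over the late window.
#'   Scale-robust and appropriate for transient evoked waveforms.
#' * `"crossing"`: each retained row's latency is estimated as the time its
#'   smoothed waveform first crosses half the level of the mean waveform's
#'   late extremum (relative to the pre-onset baseline), and the latency
#'   component is the candidate whose weights correlate most with those
#'   crossing times. Appropriate for sustained ramp-like dynamics, where the
#'   shape criterion is unreliable but single-trial amplitude variation is
#'   negligible.
#'
#' @param fit an `lfp_pca`.
#' @param window ms window over which latency is evaluated.
#' @param smooth_ms smoothing window (ms) for the derivative / the rows.
#' @param candidates component indices considered.
#' @param method identification criterion (see above).
#' @return list: `component` (index), `r` (the chosen component's signed
#'   shape correlation with the smoothed ERP derivative), `lag_cor` (signed
#'   correlation between the component's weights and waveform lateness;
#'   positive = larger weight, later waveform), `similarity` (per-candidate
#'   statistic), `method`, and for `"crossing"` the per-row latency
#'   estimates (`lags`, ms).
#' @export
latency_component <- function(fit, window = c(200, 1000), smooth_ms = 80,
                              candidates = seq_len(min(3, fit$k)),
                              method = c("derivative", "crossing")) {
  stopifnot(inherits(fit, "lfp_pca"))
  method <- match.arg(method)
  dt <- diff(fit$time_ms[1:2])
  der <- erp_derivative(fit$mean_timecourse, fs_hz = 1000 / dt,
                        smooth_ms = smooth_ms)
  sel <- fit$time_ms >= window[1] & fit$time_ms <= window[2]

  if (method == "derivative") {
    rr <- vapply(candidates, function(j) cor(fit$V[sel, j], der[sel]), 1)
    best_i <- which.max(abs(rr))
    best <- candidates[best_i]
    # a row shifted later by tau looks like -tau * dERP/dt, so weights on a
    # +derivative-aligned component index earliness
    return(list(component = best, r = rr[best_i], lag_cor = -rr[best_i],
                similarity = stats::setNames(abs(rr),
                                             paste0("PC", candidates)),
                method = method))
  }

  lag_hat <- crossing_latency(fit, window, smooth_ms)
  scores <- sweep(fit$U[, candidates, drop = FALSE], 2,
                  fit$d[candidates], `*`)
  wl <- suppressWarnings(as.numeric(cor(scores, lag_hat)))
  wl[!is.finite(wl)] <- 0
  best_i <- which.max(abs(wl))
  best <- candidates[best_i]
  list(component = best, r = cor(fit$V[sel, best], der[sel]),
       lag_cor = wl[best_i],
       similarity = stats::setNames(abs(wl), paste0("PC", candidates)),
       method = method, lags = lag_hat)
}

# per-row latency as the first crossing of half the mean waveform's late
# extremum (baseline-referenced, direction-aware); rows that never cross are
# assigned the window end
crossing_latency <- function(fit, window = c(200, 1000), smooth_ms = 80) {
  w <- max(2L, round(smooth_ms / diff(fit$time_ms[1:2])))
  Xr <- sweep(fit$U, 2, fit$d, `*`) %*% t(fit$V)
  Xr <- Xr + matrix(fit$mean_timecourse, nrow(Xr), ncol(Xr), byrow = TRUE)
  Xs <- t(apply(Xr, 1, boxcar_smooth, w = w))
  mu <- colMeans(Xs)
  pre <- fit$time_ms < 0
  if (!any(pre)) pre <- seq_len(max(2, ceiling(ncol(Xs) / 10)))
  b <- mean(mu[pre])
  sel <- which(fit$time_ms >= window[1] & fit$time_ms <= window[2])
  jext <- sel[which.max(abs(mu[sel] - b))]
  sgn <- sign(mu[jext] - b)
  thr <- b + 0.5 * (mu[jext] - b)
  tend <- fit$time_ms[sel[length(sel)]]
  vapply(seq_len(nrow(Xs)), function(i) {
    j <- which(sgn * (Xs[i, sel] - thr) >= 0)[1]
    if (is.na(j)) tend else fit$time_ms[sel][j]
  }, 1)
}

#' Indices of noise components used for control models
#'
#' Control analyses use components far down the spectrum (101 and 102 by
#' convention) whose weights carry no structured signal. When the
#' decomposition retains fewer components, the last two retained are used
#' instead, with a warning.
#'
#' @param fit an `lfp_pca`.
#' @param prefer preferred indices.
#' @return integer vector of length 2.
#' @export
noise_components <- function(fit, prefer = c(101L, 102L)) {
  if (fit$k >= max(prefer)) return(as.integer(prefer))
  warning("decomposition has only ", fit$k,
          " components; using the last two retained as noise components")
  as.integer(c(fit$k - 1L, fit$k))
}

#' Align per-subject waveform signs across subjects
#'
#' Source-reconstructed (virtual-electrode) data carry an arbitrary sign per
#' subject. This iterative procedure flips any subject whose evoked response
#' correlates negatively with the signed grand mean of the other subjects,
#' until no flip remains; the overall sign is resolved by the convention that
#' the majority sign is +1 (ties keep subject 1 positive).
#'
#' @param subject_arrays list of [lfp_array()], one per subject.
#' @param max_iter iteration cap; non-convergence raises an error with the
#'   subject correlation diagnostics attached.
#' @return integer vector of signs in {+1, -1}, one per subject.
#' @export
align_subject_signs <- function(subject_arrays, max_iter = 100) {
  ns <- length(subject_arrays)
  if (ns < 2) stop("need at least 2 subjects")
  ev <- vapply(subject_arrays, function(a) colMeans(a$data),
               numeric(ncol(subject_arrays[[1]]$data)))
  signs <- rep(1, ns)
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    for (s in seq_len(ns)) {
      others <- rowMeans(ev[, -s, drop = FALSE] *
                           rep(signs[-s], each = nrow(ev)))
      r <- cor(signs[s] * ev[, s], others)
      if (is.finite(r) && r < 0) {
        signs[s] <- -signs[s]
        changed <- TRUE
      }
    }
    if (!changed) {
      if (sum(signs < 0) > ns / 2) signs <- -signs
      if (sum(signs < 0) == ns / 2 && signs[1] < 0) signs <- -signs
      return(as.integer(signs))
    }
  }
  diag_r <- vapply(seq_len(ns), function(s)
    cor(signs[s] * ev[, s], rowMeans(ev[, -s, drop = FALSE] *
                                       rep(signs[-s], each = nrow(ev)))), 1)
  stop("sign alignment did not converge after ", max_iter,
       " iterations; subject correlations: ",
       paste(sprintf("%.2f", diag_r), collapse = ", "))
}

#' Earliness-oriented latency-component weights
#'
#' Single-trial scores of the latency component, sign-aligned so that a
#' *larger* weight means an *earlier* waveform on that trial. A latency
#' shift expresses itself, to first order, as negative admixture of the
#' ERP's temporal derivative, so scores on a derivative-aligned component
#' index earliness; the component's stored sign (which follows the anchor
#' convention) is corrected accordingly.
#'
#' @param fit an `lfp_pca`.
#' @param lat optional [latency_component()] result (recomputed otherwise).
#' @return numeric vector of oriented weights, one per retained row, with
#'   attribute `component`.
#' @export
latency_weights <- function(fit, lat = NULL) {
  if (is.null(lat)) lat <- latency_component(fit)
  # orient against the per-trial lag estimates: positive weight = earlier
  w <- coef(fit)[, lat$component]
  if (lat$lag_cor > 0) w <- -w
  structure(w, component = lat$component)
}
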