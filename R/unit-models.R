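# Build the 5-regressor decision design: a constant for effort trials, a
# constant for delay trials, left-minus-right value difference, chosen action
# (L = +1, R = -1), and chosen value. Value regressors are z-scored per
# session by default so coefficients are comparable across recordings.
decision_design <- function(trials, zscore_values = TRUE) {
  f <- if (zscore_values) zscore else identity
  X <- cbind(
    const_effort = as.numeric(trials$trial_type == "effort"),
    const_delay = as.numeric(trials$trial_type == "delay"),
    value_diff = f(trials$value_left - trials$value_right),
    choice = side_sign(trials),
    chosen_value = f(trials$chosen_value))
  empty <- colSums(X[, 1:2, drop = FALSE] != 0) == 0
  if (any(empty)) {
    warning("dropping empty trial-type constant: ",
            paste(colnames(X)[1:2][empty], collapse = ", "))
    X <- X[, !(colnames(X) %in% colnames(X)[1:2][empty]), drop = FALSE]
  }
  X
}

#' Sliding-window decision-variable regression on unit firing
#'
#' Regresses binned firing rates, across trials, on the 5-regressor decision
#' model (effort/delay constants, left-minus-right action value, chosen
#' action, chosen value) separately in every timebin, and computes the
#' coefficient of partial determination (CPD) for action value difference,
#' chosen action and chosen value. Z-statistics are retained per bin so that
#' cross-unit analyses (e.g. early value-difference vs late choice
#' selectivity) can be computed downstream.
#'
#' @param rates a [bin_rates()] object.
#' @param trials the aligned trial table.
#' @param zscore_values z-score the value regressors (default) or use raw
#'   levels.
#' @return object of class `unit_regression`: `coef`, `z` (bins x
#'   regressors), `cpd` (bins x 3 factors), `sse`, `bin_centers_ms`,
#'   `n_trials`, `factors`.
#' @export
unit_decision_model <- function(rates, trials, zscore_values = TRUE) {
  stopifnot(inherits(rates, "binned_rates"))
  if (nrow(rates$rates) != nrow(trials))
    stop("trials do not align with the rate matrix")
  X <- decision_design(trials, zscore_values)
  factors <- intersect(c("value_diff", "choice", "chosen_value"),
                       colnames(X))
  fit_timecourse(rates$rates, X, factors, rates$bin_centers_ms)
}

# shared engine: per-bin OLS + CPD for named single-column factors
fit_timecourse <- function(R, X, factors, centers) {
  nb <- ncol(R)
  p <- ncol(X)
  cf <- matrix(NA_real_, nb, p, dimnames = list(NULL, colnames(X)))
  zz <- cf
  sse <- numeric(nb)
  cpds <- matrix(NA_real_, nb, length(factors),
                 dimnames = list(NULL, factors))
  for (b in seq_len(nb)) {
    y <- R[, b]
    fit <- ols_fit(y, X)
    cf[b, ] <- fit$coefficients
    zz[b, ] <- fit$z
    sse[b] <- fit$sse
    for (fc in factors) {
      red <- ols_fit(y, X[, colnames(X) != fc, drop = FALSE])
      cpds[b, fc] <- if (red$sse > 0)
        max((red$sse - fit$sse) / red$sse, 0) else NaN
    }
  }
  structure(list(coef = cf, z = zz, cpd = cpds, sse = sse,
                 bin_centers_ms = centers, n_trials = nrow(R),
                 factors = factors, design = colnames(X)),
            class = "unit_regression")
}

#' @export
print.unit_regression <- function(x, ...) {
  pk <- apply(x$cpd, 2, function(v) x$bin_centers_ms[which.max(v)])
  cat(sprintf("<unit_regression> %d bins, %d trials; CPD peaks: %s\n",
              length(x$bin_centers_ms), x$n_trials,
              paste(sprintf("%s @ %g ms", names(pk), pk), collapse = ", ")))
  invisible(x)
}

#' @export
plot.unit_regression <- function(x, ...) {
  matplot(x$bin_centers_ms, x$cpd, type = "l", lty = 1,
          xlab = "time from choice onset (ms)", ylab = "CPD", ...)
  legend("topleft", legend = colnames(x$cpd), lty = 1,
         col = seq_len(ncol(x$cpd)), bty = "n")
  invisible(x)
}

#' Per-timepoint value regression on LFP voltage
#'
#' At every timepoint, regresses the single-trial voltage on chosen and
#' unchosen value (plus intercept), per electrode, and aggregates the
#' Z-scored coefficients as mean +/- s.e. across electrodes. Early in the
#' evoked response the two coefficients share a sign (value sum coding);
#' later they diverge (value difference coding); both peak where the ERP is
#' ramping, not at its peaks.
#'
#' @param arrays list of [lfp_array()] (or a single one).
#' @param trials trial table aligned with every array.
#' @param zscore_values z-score the value regressors.
#' @return list with `time_ms`, `z_chosen`, `z_unchosen` (electrodes x
#'   time), and `mean_z`, `se_z` (2 x time matrices).
#' @export
lfp_value_regression <- function(arrays, trials, zscore_values = TRUE) {
  if (inherits(arrays, "lfp_array")) arrays <- list(arrays)
  f <- if (zscore_values) zscore else identity
  X <- cbind(intercept = 1, chosen = f(trials$chosen_value),
             unchosen = f(trials$unchosen_value))
  ne <- length(arrays)
  np <- ncol(arrays[[1]]$data)
  zc <- matrix(NA_real_, ne, np)
  zu <- matrix(NA_real_, ne, np)
  for (e in seq_len(ne)) {
    A <- arrays[[e]]$data
    if (nrow(A) != nrow(trials)) stop("trials do not align with array ", e)
    for (tpt in seq_len(np)) {
      fit <- ols_fit(A[, tpt], X)
      zc[e, tpt] <- fit$z["chosen"]
      zu[e, tpt] <- fit$z["unchosen"]
    }
  }
  mz <- rbind(chosen = colMeans(zc), unchosen = colMeans(zu))
  sz <- rbind(chosen = apply(zc, 2, sd) / sqrt(ne),
              unchosen = apply(zu, 2, sd) / sqrt(ne))
  list(time_ms = arrays[[1]]$time_ms, z_chosen = zc, z_unchosen = zu,
       mean_z = mz, se_z = sz)
}

#' Regress single-trial component weights on decision variables
#'
#' Multiple regression of one component's single-trial weights on intercept,
#' chosen value, unchosen value and an error-trial indicator. With
#' `include_rt`, reaction time is first residualised against those three
#' regressors (orthogonalised) and appended, so its coefficient captures
#' RT variance beyond the task variables.
#'
#' @param u weight vector (one component), row-aligned with `trials`.
#' @param trials trial table (needs `rt_ms` when `include_rt`).
#' @param include_rt add the orthogonalised reaction-time regressor.
#' @param zscore_values z-score the value regressors.
#' @return data.frame with `estimate`, `se`, `z` per regressor.
#' @export
pc_weight_regression <- function(u, trials, include_rt = FALSE,
                                 zscore_values = TRUE) {
  if (length(u) != nrow(trials)) stop("weights must row-align with trials")
  f <- if (zscore_values) zscore else identity
  X <- cbind(intercept = 1, chosen_value = f(trials$chosen_value),
             unchosen_value = f(trials$unchosen_value),
             error = as.numeric(trials$is_error))
  if (all(X[, "error"] == 0)) {
    warning("no error trials; dropping the error regressor")
    X <- X[, colnames(X) != "error", drop = FALSE]
  }
  if (include_rt) {
    if (all(is.na(trials$rt_ms))) stop("trials carry no reaction times")
    rt <- orthogonalize(trials$rt_ms, X[, -1, drop = FALSE])
    X <- cbind(X, rt = rt)
  }
  fit <- ols_fit(u, X)
  data.frame(regressor = names(fit$coefficients),
             estimate = fit$coefficients, se = fit$se, z = fit$z,
             row.names = NULL)
}
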