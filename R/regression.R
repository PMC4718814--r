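#' Ordinary least squares with classical standard errors
#'
#' Thin wrapper around a QR solve that returns exactly what the sliding-bin
#' analyses need: coefficients, classical standard errors, Z-statistics
#' (coefficient / SE) and the sum of squared errors. The design must be full
#' column rank; rank deficiency is an error naming the collinear columns.
#'
#' @param y response vector.
#' @param X design matrix (with colnames; an intercept is *not* added).
#' @return list with `coefficients`, `se`, `z`, `sse`, `df_residual`,
#'   `fitted`, `residuals`.
#' @export
ols_fit <- function(y, X) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qq <- qr(X)
  if (qq$rank < ncol(X)) {
    bad <- colnames(X)[qq$pivot[(qq$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qq, y)
  res <- y - X %*% beta
  sse <- sum(res^2)
  df <- length(y) - ncol(X)
  sigma2 <- if (df > 0) sse / df else NA_real_
  XtXi <- chol2inv(chol(crossprod(X)))
  se <- sqrt(pmax(diag(XtXi), 0) * sigma2)
  z <- as.numeric(beta) / se
  list(coefficients = stats::setNames(as.numeric(beta), colnames(X)),
       se = stats::setNames(se, colnames(X)),
       z = stats::setNames(z, colnames(X)),
       sse = sse, df_residual = df,
       fitted = as.numeric(X %*% beta), residuals = as.numeric(res))
}

#' Coefficient of partial determination
#'
#' Fraction of residual variance uniquely explained by a factor:
#' `CPD = [SSE(reduced) - SSE(full)] / SSE(reduced)`, where the reduced model
#' drops the factor's columns. Lies in [0, 1] for nested OLS fits. If the
#' reduced model already fits perfectly (SSE = 0) the quantity is undefined
#' and `NaN` is returned with a warning.
#'
#' @param y response vector.
#' @param X_full full design matrix.
#' @param factor_columns column indices or names of the factor of interest.
#' @return CPD in [0, 1], or flagged `NaN`.
#' @export
cpd <- function(y, X_full, factor_columns) {
  X_full <- as.matrix(X_full)
  if (is.character(factor_columns))
    factor_columns <- match(factor_columns, colnames(X_full))
  if (any(is.na(factor_columns))) stop("unknown factor columns")
  full <- ols_fit(y, X_full)
  red <- ols_fit(y, X_full[, -factor_columns, drop = FALSE])
  if (red$sse <= 0) {
    warning("reduced model has zero SSE; CPD undefined")
    return(NaN)
  }
  max((red$sse - full$sse) / red$sse, 0)
}

#' Sliding-bin firing rates from a spike raster
#'
#' Boxcar rate estimate: the spike count in a window of `bin_width` ms
#' centred on each bin centre, divided by the width. Bin centres run in
#' `step` ms increments across the raster window.
#'
#' @param raster a [spike_raster()].
#' @param bin_width boxcar width in ms (> 0); 200 ms default.
#' @param step centre-to-centre spacing in ms.
#' @param window optional analysis window for the bin centres (defaults to
#'   the raster window shrunk by half a bin at each end).
#' @return object of class `binned_rates`: `rates` (trials x bins, Hz),
#'   `bin_centers_ms`, `bin_width_ms`, plus the raster's metadata.
#' @export
bin_rates <- function(raster, bin_width = 200, step = 10, window = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  if (bin_width <= 0) stop("bin width must be positive")
  if (is.null(window))
    window <- c(raster$window[1] + bin_width / 2,
                raster$window[2] - bin_width / 2)
  centers <- seq(window[1], window[2], by = step)
  lo <- centers - bin_width / 2
  hi <- centers + bin_width / 2
  rates <- t(vapply(raster$spike_times, function(s) {
    if (!length(s)) return(numeric(length(centers)))
    (findInterval(hi - 1e-9, s) - findInterval(lo - 1e-9, s)) /
      bin_width * 1000
  }, numeric(length(centers))))
  structure(list(rates = rates, bin_centers_ms = centers,
                 bin_width_ms = bin_width, unit_id = raster$unit_id,
                 region = raster$region, electrode_id = raster$electrode_id),
            class = "binned_rates")
}

#' @export
print.binned_rates <- function(x, ...) {
  cat(sprintf("<binned_rates> unit %s: %d trials x %d bins (%g ms boxcar)\n",
              x$unit_id, nrow(x$rates), length(x$bin_centers_ms),
              x$bin_width_ms))
  invisible(x)
}

#' Smoothed temporal derivative of a waveform
#'
#' Centred finite difference followed by a boxcar average over `smooth_ms`.
#' Used to locate when the evoked response is ramping (large derivative)
#' rather than peaking, and as the latency-component similarity target.
#'
#' @param mean_erp waveform (uniformly sampled).
#' @param fs_hz sampling rate.
#' @param smooth_ms boxcar width in ms; must cover at least 2 samples.
#' @return derivative in units per ms, same length as input.
#' @export
erp_derivative <- function(mean_erp, fs_hz, smooth_ms = 80) {
  dt <- 1000 / fs_hz
  w <- round(smooth_ms / dt)
  if (w < 2) stop("smoothing window shorter than 2 samples")
  n <- length(mean_erp)
  d <- numeric(n)
  d[2:(n - 1)] <- (mean_erp[3:n] - mean_erp[1:(n - 2)]) / (2 * dt)
  d[1] <- (mean_erp[2] - mean_erp[1]) / dt
  d[n] <- (mean_erp[n] - mean_erp[n - 1]) / dt
  boxcar_smooth(d, w)
}

# centered moving average with shrinking windows at the edges
boxcar_smooth <- function(x, w) {
  n <- length(x)
  half <- floor(w / 2)
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  for (i in seq_len(n)) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    out[i] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  out
}

#' Residualise a vector against a set of covariates
#'
#' Returns `x` minus its projection onto the span of `Z` plus an intercept.
#'
#' @param x numeric vector.
#' @param Z matrix (or vector) of covariates, row-aligned with `x`.
#' @return residual vector, orthogonal to every column of `Z` and to the
#'   constant.
#' @export
orthogonalize <- function(x, Z) {
  Z <- cbind(intercept = 1, as.matrix(Z))
  if (nrow(Z) != length(x)) stop("rows of Z must match length of x")
  qq <- qr(Z)
  as.numeric(qr.resid(qq, x))
}
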