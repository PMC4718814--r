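#' Sign-flip permutation test for a population effect
#'
#' Non-parametric one-sided test of whether the mean of per-unit effects
#' (e.g. CPD minus its mean over a pre-choice baseline) exceeds zero. The
#' null distribution is built by randomly flipping the sign of each unit's
#' whole effect timecourse and averaging; the p-value at each timebin is
#' `(#{permuted means >= observed mean} + 1) / (n_perm + 1)`, so it is
#' bounded below by `1/(n_perm + 1)`.
#'
#' @param effects units x timebins matrix; a plain vector is treated as a
#'   single timebin across units.
#' @param n_perm number of permutations (default 10000).
#' @param seed optional seed.
#' @return numeric vector of one-sided p-values, one per timebin.
#' @export
signflip_test <- function(effects, n_perm = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(derive_seed(seed, "signflip"))
  E <- as.matrix(effects)
  n_units <- nrow(E)
  if (n_units < 2) stop("need effects from at least 2 units")
  obs <- colMeans(E)
  S <- matrix(sample(c(-1, 1), n_perm * n_units, replace = TRUE),
              n_perm, n_units)
  perm_means <- (S %*% E) / n_units
  ge <- perm_means >= rep(obs, each = n_perm) - 1e-12
  (colSums(ge) + 1) / (n_perm + 1)
}

#' Empirical multiple-comparison Z thresholds across time
#'
#' Estimates the significance criterion that controls for multiple
#' comparisons over a time window directly from the data: the regression is
#' refitted many times with the design matrix rows (whole trials) permuted,
#' preserving the covariance among regressors; the thresholds are the
#' (1 - alpha) quantile of the maximum Z and the alpha quantile of the
#' minimum Z of the regressor of interest over the window.
#'
#' @param rates a [bin_rates()] object.
#' @param design design matrix (trials x p) including the regressor of
#'   interest.
#' @param interest column name or index of the regressor of interest.
#' @param window `c(t0, t1)` ms window over which the max/min are taken.
#' @param alpha family-wise error target (one-sided, each tail).
#' @param n_perm number of permutations; must satisfy `n_perm * alpha >= 1`.
#' @param seed optional seed.
#' @return list: `z_pos`, `z_neg` (thresholds), `max_z`, `min_z` (the
#'   permutation distributions).
#' @export
empirical_threshold <- function(rates, design, interest,
                                window = c(250, 750), alpha = 0.01,
                                n_perm = 1000, seed = NULL) {
  stopifnot(inherits(rates, "binned_rates"))
  if (n_perm * alpha < 1)
    stop("n_perm too small to estimate the ", alpha, " quantile")
  if (!is.null(seed)) set.seed(derive_seed(seed, "threshold"))
  X <- as.matrix(design)
  if (is.character(interest)) interest <- match(interest, colnames(X))
  sel <- rates$bin_centers_ms >= window[1] & rates$bin_centers_ms <= window[2]
  if (!any(sel)) stop("window outside the bin axis")
  R <- rates$rates[, sel, drop = FALSE]
  n <- nrow(X)
  max_z <- numeric(n_perm)
  min_z <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    Xp <- X[sample.int(n), , drop = FALSE]
    zs <- vapply(seq_len(ncol(R)),
                 function(b) ols_fit(R[, b], Xp)$z[interest], 1)
    max_z[p] <- max(zs)
    min_z[p] <- min(zs)
  }
  list(z_pos = as.numeric(quantile(max_z, 1 - alpha, type = 1)),
       z_neg = as.numeric(quantile(min_z, alpha, type = 1)),
       max_z = max_z, min_z = min_z)
}

#' Circular-linear correlation
#'
#' Association between an angular variable (e.g. oscillatory phase) and a
#' linear variable, via the two-harmonic construction:
#' `r = sqrt[(r_cx^2 + r_sx^2 - 2 r_cx r_sx r_cs) / (1 - r_cs^2)]` with
#' `r_cx = cor(cos theta, x)`, `r_sx = cor(sin theta, x)`,
#' `r_cs = cor(cos theta, sin theta)`. Equivalently the square root of the
#' R^2 from regressing x on cos(theta) and sin(theta). Non-negative by
#' construction and invariant to phase rotation.
#'
#' @param theta phases in radians.
#' @param x linear variable, same length (>= 3).
#' @return r in [0, 1]; `NaN` (with a warning) if `x` has zero variance.
#' @export
circ_linear_corr <- function(theta, x) {
  if (length(theta) != length(x) || length(x) < 3)
    stop("theta and x must have equal length >= 3")
  if (sd(x) == 0) {
    warning("x has zero variance; circular-linear correlation undefined")
    return(NaN)
  }
  rcx <- cor(cos(theta), x)
  rsx <- cor(sin(theta), x)
  rcs <- cor(cos(theta), sin(theta))
  r2 <- (rcx^2 + rsx^2 - 2 * rcx * rsx * rcs) / (1 - rcs^2)
  min(max(sqrt(max(r2, 0)), 0), 1)
}
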