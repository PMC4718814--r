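# ---- regressor registry ----------------------------------------------------
# The "full" task-covariate set is a named registry of column builders so
# users can add session-specific covariates. The default full set contains
# the reduced 6-term decision model plus documented, mutually non-collinear
# task covariates (19 columns in total). Headline analyses are expected to
# give similar answers under `reduced6` -- tests enforce this on synthetic
# data.

full_registry <- function() {
  list(
    unchosen_value = function(tr, f) f(tr$unchosen_value),
    reward_sum = function(tr, f) f(tr$reward_left + tr$reward_right),
    reward_diff = function(tr, f) f(tr$reward_left - tr$reward_right),
    is_error = function(tr, f) as.numeric(tr$is_error),
    trial_index = function(tr, f) f(seq_len(nrow(tr))),
    prev_choice = function(tr, f) c(0, side_sign(tr)[-nrow(tr)]),
    prev_chosen_value = function(tr, f) c(0, f(tr$chosen_value)[-nrow(tr)]),
    prev_error = function(tr, f) c(0, as.numeric(tr$is_error)[-nrow(tr)]),
    prev_type = function(tr, f)
      c(0, as.numeric(tr$trial_type == "effort")[-nrow(tr)]),
    choice_x_chosen_value = function(tr, f) side_sign(tr) * f(tr$chosen_value),
    # note: choice * unchosen value is deliberately absent -- together with
    # choice and choice * chosen value it would span value_diff exactly
    chosen_reward = function(tr, f)
      f(ifelse(tr$chosen_side == "L", tr$reward_left, tr$reward_right)),
    type_x_chosen_value = function(tr, f)
      ifelse(tr$trial_type == "effort", 1, -1) * f(tr$chosen_value),
    type_x_value_diff = function(tr, f)
      ifelse(tr$trial_type == "effort", 1, -1) *
        f(tr$value_left - tr$value_right),
    type_x_choice = function(tr, f)
      ifelse(tr$trial_type == "effort", 1, -1) * side_sign(tr)
  )
}

#' Task design matrix for coupling analyses
#'
#' `reduced6`: effort constant, delay constant, chosen action, left-minus-
#' right action value, chosen value (the 6-coregressor model; one constant
#' is dropped automatically when a session has a single trial type).
#' `full19`: the reduced set plus the extensible covariate registry.
#'
#' @param trials trial table.
#' @param set `"reduced6"` or `"full19"`.
#' @param registry named list of `function(trials, f)` column builders used
#'   by `full19`; defaults to the built-in set.
#' @param zscore_values z-score value-type regressors.
#' @return design matrix with named columns.
#' @export
task_design <- function(trials, set = c("reduced6", "full19"),
                        registry = full_registry(), zscore_values = TRUE) {
  set <- match.arg(set)
  f <- if (zscore_values) zscore else identity
  X <- decision_design(trials, zscore_values)
  if (set == "full19") {
    extra <- vapply(registry, function(b) b(trials, f),
                    numeric(nrow(trials)))
    X <- cbind(X, extra)
  }
  X
}

#' Unit regression augmented with LFP-derived component weights
#'
#' Adds single-trial PC weights (from a *different*, simultaneously recorded
#' electrode) to the task design and returns the per-bin CPD of the PC
#' term(s), after partialling out all task covariates. This is the statistic
#' linking mesoscopic waveform dynamics to unit firing.
#'
#' @param rates a [bin_rates()] object.
#' @param trials aligned trial table.
#' @param pc_weights vector (one component) or matrix (columns = components)
#'   of per-trial weights.
#' @param set task-covariate set (`"reduced6"` or `"full19"`).
#' @param ... passed to [task_design()].
#' @return a `unit_regression` whose `cpd` has one column, `pc`, the joint
#'   CPD of the PC regressors; plus a `pc_z` matrix of their Z-statistics.
#' @export
augmented_unit_model <- function(rates, trials, pc_weights,
                                 set = "reduced6", ...) {
  stopifnot(inherits(rates, "binned_rates"))
  W <- as.matrix(pc_weights)
  if (nrow(W) != nrow(trials)) stop("pc weights must row-align with trials")
  colnames(W) <- paste0("pc", seq_len(ncol(W)))
  X <- cbind(task_design(trials, set, ...), W)
  R <- rates$rates
  nb <- ncol(R)
  cpds <- numeric(nb)
  pc_z <- matrix(NA_real_, nb, ncol(W), dimnames = list(NULL, colnames(W)))
  for (b in seq_len(nb)) {
    y <- R[, b]
    fit <- ols_fit(y, X)
    red <- ols_fit(y, X[, !(colnames(X) %in% colnames(W)), drop = FALSE])
    cpds[b] <- if (red$sse > 0) max((red$sse - fit$sse) / red$sse, 0) else NaN
    pc_z[b, ] <- fit$z[colnames(W)]
  }
  structure(list(coef = NULL, z = NULL,
                 cpd = matrix(cpds, nb, 1, dimnames = list(NULL, "pc")),
                 pc_z = pc_z, sse = NULL, bin_centers_ms = rates$bin_centers_ms,
                 n_trials = nrow(R), factors = "pc",
                 design = colnames(X)),
            class = "unit_regression")
}

#' CPD reduction attributable to the top components
#'
#' Compares two augmented decision models: one including the top (PC1/PC2)
#' weights as coregressors, one including noise-component weights (PC101/102
#' or equivalent) as a control for the generic effect of adding regressors.
#' `delta_cpd(factor) = CPD(factor | control model) - CPD(factor | PC model)`
#' per bin: positive values mean the top components explain away that
#' factor's variance. The reduction is bounded above by the control-model
#' CPD itself.
#'
#' @param rates a [bin_rates()] object.
#' @param trials aligned trial table.
#' @param pcs_12 matrix of top-component weights (trials x k, usually k = 2).
#' @param control_pcs matrix of noise-component weights, same shape.
#' @param set task-covariate set.
#' @param ... passed to [task_design()].
#' @return list: `delta_cpd` (bins x factors), `cpd_pc_model`,
#'   `cpd_control_model`, `bin_centers_ms`, `factors`.
#' @export
cpd_reduction <- function(rates, trials, pcs_12, control_pcs,
                          set = "reduced6", ...) {
  stopifnot(inherits(rates, "binned_rates"))
  P <- as.matrix(pcs_12); C <- as.matrix(control_pcs)
  stopifnot(nrow(P) == nrow(trials), nrow(C) == nrow(trials))
  colnames(P) <- paste0("pc", seq_len(ncol(P)))
  colnames(C) <- paste0("ctl", seq_len(ncol(C)))
  Xt <- task_design(trials, set, ...)
  factors <- intersect(c("value_diff", "choice", "chosen_value"),
                       colnames(Xt))
  m_pc <- fit_timecourse(rates$rates, cbind(Xt, P), factors,
                         rates$bin_centers_ms)
  m_ctl <- fit_timecourse(rates$rates, cbind(Xt, C), factors,
                          rates$bin_centers_ms)
  list(delta_cpd = m_ctl$cpd - m_pc$cpd,
       cpd_pc_model = m_pc$cpd, cpd_control_model = m_ctl$cpd,
       bin_centers_ms = rates$bin_centers_ms, factors = factors)
}

#' Shuffle PC weights while preserving their chosen-value correlation
#'
#' Permutes weights across trials *within chosen-value strata*: trial-
#' specific coupling to firing is destroyed while the weights' correlation
#' with chosen value is preserved (up to stratum sampling error). Singleton
#' strata are left in place.
#'
#' @param pc_weights vector or matrix of per-trial weights.
#' @param trials trial table supplying the chosen-value strata.
#' @param seed optional seed.
#' @return shuffled weights, same shape.
#' @export
shuffled_pc_control <- function(pc_weights, trials, seed = NULL) {
  if (!is.null(seed)) set.seed(derive_seed(seed, "shuffle"))
  W <- as.matrix(pc_weights)
  stopifnot(nrow(W) == nrow(trials))
  out <- W
  for (v in unique(trials$chosen_value)) {
    rows <- which(trials$chosen_value == v)
    if (length(rows) > 1)
      out[rows, ] <- W[sample(rows), , drop = FALSE]
  }
  if (is.null(dim(pc_weights))) out[, 1] else out
}

#' Local-vs-distal attribution of the CPD reduction
#'
#' Orthogonalises local component weights with respect to distal ones, runs
#' [cpd_reduction()], then performs the reverse analysis (distal
#' orthogonalised to local) and subtracts it. Positive values mean local
#' dynamics explain away more task variance than distal dynamics.
#'
#' @param rates,trials as in [cpd_reduction()].
#' @param local_pcs,distal_pcs trials x k weight matrices from the local and
#'   distal region.
#' @param control_pcs noise-component weights for both directions.
#' @param ... passed to [cpd_reduction()].
#' @return list: `ddelta_cpd` (bins x factors; local minus distal),
#'   `local` and `distal` full [cpd_reduction()] results.
#' @export
local_vs_distal <- function(rates, trials, local_pcs, distal_pcs,
                            control_pcs, ...) {
  L <- as.matrix(local_pcs); D <- as.matrix(distal_pcs)
  L_orth <- apply(L, 2, orthogonalize, Z = D)
  D_orth <- apply(D, 2, orthogonalize, Z = L)
  r_loc <- cpd_reduction(rates, trials, L_orth, control_pcs, ...)
  r_dis <- cpd_reduction(rates, trials, D_orth, control_pcs, ...)
  list(ddelta_cpd = r_loc$delta_cpd - r_dis$delta_cpd,
       local = r_loc, distal = r_dis,
       bin_centers_ms = r_loc$bin_centers_ms)
}

#' Cross-regional effort/delay coupling model
#'
#' Six-column design explaining one region's unit firing from the latency
#' weights of two source regions, split by trial type: effort and delay
#' constants, source-1 weights gated to effort and to delay trials, and
#' source-2 weights gated likewise. Reports the per-bin CPD of each gated
#' term and the effort-minus-delay CPD difference per source.
#'
#' @param rates a [bin_rates()] object (target region units).
#' @param trials aligned trial table.
#' @param source1_pc2,source2_pc2 per-trial latency-component weights from
#'   the two source regions.
#' @param source_names labels for the two sources.
#' @return list: `cpd` (bins x 4 gated terms), `effort_minus_delay` (bins x
#'   2 sources), `bin_centers_ms`.
#' @export
cross_region_model <- function(rates, trials, source1_pc2, source2_pc2,
                               source_names = c("source1", "source2")) {
  stopifnot(inherits(rates, "binned_rates"),
            length(source1_pc2) == nrow(trials),
            length(source2_pc2) == nrow(trials))
  eff <- as.numeric(trials$trial_type == "effort")
  del <- 1 - eff
  if (!any(eff == 1) || !any(del == 1))
    stop("cross-region model needs both trial types")
  X <- cbind(const_effort = eff, const_delay = del,
             s1_effort = source1_pc2 * eff, s1_delay = source1_pc2 * del,
             s2_effort = source2_pc2 * eff, s2_delay = source2_pc2 * del)
  terms <- colnames(X)[3:6]
  m <- fit_timecourse(rates$rates, X, terms, rates$bin_centers_ms)
  emd <- cbind(m$cpd[, "s1_effort"] - m$cpd[, "s1_delay"],
               m$cpd[, "s2_effort"] - m$cpd[, "s2_delay"])
  colnames(emd) <- source_names
  list(cpd = m$cpd, z = m$z, effort_minus_delay = emd,
       bin_centers_ms = rates$bin_centers_ms, source_names = source_names)
}

#' Median split of units by a selectivity measure
#'
#' Deterministic split into low/high groups of sizes ceiling(n/2) and
#' floor(n/2): stable sort, ties go to the lower half.
#'
#' @param selectivity per-unit scalar (e.g. peak chosen-value CPD).
#' @return list with integer index vectors `low` and `high`.
#' @export
median_split <- function(selectivity) {
  n <- length(selectivity)
  ord <- order(selectivity, seq_len(n))  # stable: ties keep original order
  n_low <- ceiling(n / 2)
  list(low = sort(ord[seq_len(n_low)]),
       high = sort(ord[(n_low + 1):n]))
}

#' Cross-electrode correlation of single-trial component weights
#'
#' Pearson correlation of trial-aligned weights for every electrode pair,
#' grouped within vs between regions, with group medians. Shared dynamics
#' show up as positive correlations that are larger within a region.
#'
#' @param weights list of per-trial weight vectors, one per electrode.
#' @param regions character vector of region labels, one per electrode.
#' @return list: `pairs` data.frame (i, j, region_i, region_j, scope, r) and
#'   `medians` named vector (within, between).
#' @export
pc_weight_cross_correlation <- function(weights, regions) {
  ne <- length(weights)
  stopifnot(length(regions) == ne, ne >= 2)
  rows <- list()
  for (i in seq_len(ne - 1)) {
    for (j in (i + 1):ne) {
      if (length(weights[[i]]) != length(weights[[j]])) next
      rows[[length(rows) + 1]] <- data.frame(
        i = i, j = j, region_i = regions[i], region_j = regions[j],
        scope = if (regions[i] == regions[j]) "within" else "between",
        r = cor(weights[[i]], weights[[j]]),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  med <- c(within = median(pairs$r[pairs$scope == "within"]),
           between = median(pairs$r[pairs$scope == "between"]))
  list(pairs = pairs, medians = med)
}

#' Analytic chance level for the CPD
#'
#' Expected CPD of an uninformative factor: roughly `p_factor / (n - p_total)`
#' for a design with `p_total` columns on `n` trials. Reported alongside
#' empirical CPDs so "at chance" statements are concrete.
#'
#' @param n_trials trials entering each fit.
#' @param p_total total number of design columns.
#' @param p_factor number of columns in the factor of interest.
#' @export
chance_cpd <- function(n_trials, p_total, p_factor = 1) {
  p_factor / (n_trials - p_total)
}
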