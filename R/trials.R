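#' Simulate a trial table for a cost-benefit choice session
#'
#' Each trial offers two pictures (left/right) carrying a reward level and a
#' cost level, both on a 1--4 scale. Option value is reward level minus cost
#' level (range -3..3). On half of the trials the cost is physical effort, on
#' the other half delay to reward; the two trial types are randomly
#' interleaved. Choices follow a softmax (logistic) on the left-minus-right
#' value difference.
#'
#' @param n_trials number of trials (>= 1).
#' @param softmax_temperature temperature of the logistic choice rule;
#'   P(choose left) = plogis((value_left - value_right) / temperature).
#'   Must be > 0; small values approach a deterministic argmax.
#' @param seed integer master seed; `NULL` leaves the RNG state alone.
#' @param session_id session identifier stored on every trial.
#' @return a `data.frame` of class `trial_table` with columns `trial_id`,
#'   `session_id`, `trial_type` ("effort"/"delay"), `reward_left`,
#'   `reward_right`, `cost_left`, `cost_right`, `value_left`, `value_right`,
#'   `chosen_side` ("L"/"R"), `chosen_value`, `unchosen_value`, `is_error`
#'   (chose the strictly lower-valued option) and `rt_ms` (NA here;
#'   populated by [sim_meg_subjects()]).
#' @examples
#' tr <- sim_trials(100, seed = 1)
#' mean(tr$is_error)
#' @export
sim_trials <- function(n_trials, softmax_temperature = 1, seed = NULL,
                       session_id = 1L) {
  stopifnot(n_trials >= 1)
  if (!is.numeric(softmax_temperature) || softmax_temperature <= 0)
    stop("softmax_temperature must be a positive real")
  if (!is.null(seed)) set.seed(derive_seed(seed, "trials"))

  n <- as.integer(n_trials)
  trial_type <- ifelse(runif(n) < 0.5, "effort", "delay")
  reward_left  <- sample.int(4L, n, replace = TRUE)
  reward_right <- sample.int(4L, n, replace = TRUE)
  cost_left    <- sample.int(4L, n, replace = TRUE)
  cost_right   <- sample.int(4L, n, replace = TRUE)
  value_left  <- reward_left - cost_left
  value_right <- reward_right - cost_right

  dv <- (value_left - value_right) / softmax_temperature
  p_left <- plogis(dv)
  # exact ties give dv = 0, p = 0.5, even in the temperature -> 0 limit
  p_left[value_left == value_right] <- 0.5
  chose_left <- runif(n) < p_left
  chosen_side <- ifelse(chose_left, "L", "R")
  chosen_value   <- ifelse(chose_left, value_left, value_right)
  unchosen_value <- ifelse(chose_left, value_right, value_left)

  out <- data.frame(
    trial_id = seq_len(n),
    session_id = as.integer(session_id),
    trial_type = trial_type,
    reward_left = reward_left, reward_right = reward_right,
    cost_left = cost_left, cost_right = cost_right,
    value_left = value_left, value_right = value_right,
    chosen_side = chosen_side,
    chosen_value = chosen_value, unchosen_value = unchosen_value,
    is_error = chosen_value < unchosen_value,
    rt_ms = NA_real_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("trial_table", "data.frame")
  out
}

# z-score with a guard for zero-variance input
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# chosen side as +1 (left) / -1 (right)
side_sign <- function(trials) ifelse(trials$chosen_side == "L", 1, -1)
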