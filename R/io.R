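#' Write a simulated dataset to a plain-text directory container
#'
#' On-disk layout: `trials.csv` (the trial table), one
#' `lfp_<region>_<electrode>.csv` matrix per electrode (rows = trials,
#' columns = samples; the header row stores the time axis in ms),
#' `truth.csv` (the ground-truth latent table) and
#' `spikes_<unit>.csv` (trial, spike_time_ms) per unit. Everything is
#' readable by any language; [read_dataset()] restores the package objects.
#'
#' @param path directory to create.
#' @param trials trial table.
#' @param lfp list of [lfp_array()] (optional).
#' @param spikes list of [spike_raster()] (optional).
#' @param truth ground-truth latent table (optional).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(path, trials, lfp = NULL, spikes = NULL,
                          truth = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write.csv(trials, file.path(path, "trials.csv"), row.names = FALSE)
  if (!is.null(truth))
    write.csv(truth, file.path(path, "truth.csv"), row.names = FALSE)
  for (a in lfp %||% list()) {
    m <- a$data
    colnames(m) <- sprintf("t%g", a$time_ms)
    fn <- sprintf("lfp_%s_%s.csv", a$region, a$electrode_id)
    utils::write.table(
      cbind(fs_hz = a$fs_hz, session_id = a$session_id, m),
      file.path(path, fn), sep = ",", row.names = FALSE)
  }
  for (s in spikes %||% list()) {
    rows <- do.call(rbind, lapply(seq_along(s$spike_times), function(i) {
      if (!length(s$spike_times[[i]])) return(NULL)
      data.frame(trial = i, spike_time_ms = s$spike_times[[i]])
    }))
    if (is.null(rows))
      rows <- data.frame(trial = integer(0), spike_time_ms = numeric(0))
    attr(rows, "window") <- s$window
    fn <- sprintf("spikes_%s_%s.csv", s$region, s$unit_id)
    write.csv(rbind(data.frame(trial = -1, spike_time_ms = s$window),
                    rows), file.path(path, fn), row.names = FALSE)
  }
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path container directory.
#' @param n_trials number of trials (defaults to the trial table's rows);
#'   needed to restore empty rasters.
#' @return list with `trials`, `lfp` (list of [lfp_array()]), `spikes`
#'   (list of [spike_raster()]) and `truth` (or NULL).
#' @export
read_dataset <- function(path, n_trials = NULL) {
  trials <- read.csv(file.path(path, "trials.csv"),
                     stringsAsFactors = FALSE)
  class(trials) <- c("trial_table", "data.frame")
  if (is.null(n_trials)) n_trials <- nrow(trials)
  truth_fn <- file.path(path, "truth.csv")
  truth <- if (file.exists(truth_fn)) read.csv(truth_fn) else NULL

  lfp <- list()
  for (fn in sort(list.files(path, "^lfp_.*\\.csv$", full.names = TRUE))) {
    m <- as.matrix(read.csv(fn, check.names = FALSE))
    meta <- strsplit(sub("\\.csv$", "", basename(fn)), "_")[[1]]
    tms <- as.numeric(sub("^t", "", colnames(m)[-(1:2)]))
    lfp[[length(lfp) + 1]] <- lfp_array(
      m[, -(1:2), drop = FALSE], tms, m[1, "fs_hz"],
      electrode_id = meta[3], region = meta[2],
      session_id = m[1, "session_id"])
  }
  spikes <- list()
  for (fn in sort(list.files(path, "^spikes_.*\\.csv$",
                             full.names = TRUE))) {
    d <- read.csv(fn)
    meta <- strsplit(sub("\\.csv$", "", basename(fn)), "_")[[1]]
    win <- d$spike_time_ms[d$trial == -1]
    d <- d[d$trial != -1, , drop = FALSE]
    st <- lapply(seq_len(n_trials), function(i)
      d$spike_time_ms[d$trial == i])
    spikes[[length(spikes) + 1]] <- spike_raster(
      st, window = win, unit_id = meta[3], region = meta[2])
  }
  list(trials = trials, lfp = lfp, spikes = spikes, truth = truth)
}
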