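#' Write / read a trial log as CSV
#'
#' Plain CSV with one row per trial and the columns documented in
#' [build_schedule()].
#'
#' @param log A `trial_log`.
#' @param path Output path.
#' @return `path`, invisibly (write) or the `trial_log` (read).
#' @export
write_trial_log <- function(log, path) {
  stopifnot(inherits(log, "trial_log"))
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("trial", "set", "trial_in_set", "stimulus_id", "cell",
              "exposure_idx", "iti_ms", "probe", "rating")
  if (!all(needed %in% names(log)))
    stop("missing trial-log columns: ",
         paste(setdiff(needed, names(log)), collapse = ", "))
  log$rating <- as.integer(log$rating)
  class(log) <- c("trial_log", "data.frame")
  log
}

#' Write / read an epoch set (CSV matrix + JSON sidecar)
#'
#' The sample matrix goes to `<path>.csv` (one row per epoch, one column
#' per sample, full double precision, no header); recording parameters and
#' per-epoch metadata go to `<path>.json`. The pair round-trips through
#' [read_epoch_set()] exactly up to 17-significant-digit decimal
#' representation.
#'
#' @param epochs An `epoch_set`.
#' @param path Base path (without extension).
#' @return `path`, invisibly (write) or the `epoch_set` (read).
#' @export
write_epoch_set <- function(epochs, path) {
  check_epochs(epochs)
  utils::write.table(format(epochs$data, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     paste0(path, ".csv"), sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  sidecar <- list(
    srate = epochs$srate,
    times_ms = list(first = epochs$times_ms[1],
                    last = epochs$times_ms[length(epochs$times_ms)]),
    sound_onset_ms = epochs$sound_onset_ms,
    channel = epochs$channel,
    n_epochs = nrow(epochs$data), n_samples = ncol(epochs$data),
    meta = epochs$meta
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  data <- as.matrix(utils::read.table(paste0(path, ".csv"), sep = ",",
                                      header = FALSE,
                                      colClasses = "numeric"))
  dimnames(data) <- NULL
  if (nrow(data) != sidecar$n_epochs || ncol(data) != sidecar$n_samples)
    stop("epoch matrix dimensions disagree with the JSON sidecar")
  meta <- as.data.frame(sidecar$meta)
  structure(list(data = data,
                 times_ms = seq(sidecar$times_ms$first,
                                sidecar$times_ms$last),
                 srate = sidecar$srate,
                 sound_onset_ms = sidecar$sound_onset_ms,
                 channel = sidecar$channel, meta = meta),
            class = "epoch_set")
}

#' Write a sweep as tidy CSV
#'
#' Long-format curve table (`swept_name`, `swept_value`, `n`, `gain`) with
#' a commented header line carrying the fixed parameters; optionally a
#' second CSV of integrated totals.
#'
#' @param result A `gain_sweep`.
#' @param path Output CSV path.
#' @param integrated_path Optional path for the `(swept_value, total_gain,
#'   total_gain_sum)` table.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(result, path, integrated_path = NULL) {
  if (!inherits(result, "gain_sweep")) stop("result must be a gain_sweep")
  fx <- result$spec$fixed
  hdr <- sprintf(
    "# varying=%s noise=%g learning_rate=%g fixed_uncertainty=%g fixed_prediction_error=%g",
    result$spec$varying, fx$noise, fx$learning_rate,
    fx$initial_uncertainty, fx$initial_prediction_error)
  con <- file(path, "w")
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(result), con, row.names = FALSE)
  close(con)
  if (!is.null(integrated_path)) {
    utils::write.csv(
      data.frame(swept_value = result$spec$values,
                 total_gain = unname(result$integrated),
                 total_gain_sum = unname(result$integrated_sum)),
      integrated_path, row.names = FALSE)
  }
  invisible(path)
}
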