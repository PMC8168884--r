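#' Band-pass filter specification
#'
#' @param band Length-2 pass band in Hz (default 0.1-20, the standard ERP
#'   band for P300 work).
#' @param order Butterworth design order passed to [signal::butter()]; the
#'   band-pass transfer function has twice this order.
#' @param zero_phase Apply forward-backward ([signal::filtfilt()]) so peak
#'   latencies are not biased; one-pass [signal::filter()] otherwise.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(band = c(0.1, 20), order = 2L, zero_phase = TRUE) {
  stopifnot(is.numeric(band), length(band) == 2L, all(is.finite(band)))
  if (band[1] <= 0 || band[1] >= band[2]) stop("band must satisfy 0 < low < high")
  structure(list(band = band, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

check_epochs <- function(epochs) {
  if (!inherits(epochs, "epoch_set")) stop("epochs must be an epoch_set")
  epochs
}

#' Band-pass filter the epochs
#'
#' Removes each epoch's mean (DC offset), then applies the Butterworth
#' band-pass, zero-phase by default. Metadata are preserved.
#'
#' @param epochs An `epoch_set`.
#' @param spec A [filter_spec()].
#' @return The filtered `epoch_set`.
#' @export
bandpass <- function(epochs, spec = filter_spec()) {
  check_epochs(epochs)
  if (!inherits(spec, "filter_spec")) stop("spec must be a filter_spec")
  nyq <- epochs$srate / 2
  if (spec$band[2] >= nyq)
    stop("upper band edge must be below the Nyquist frequency")
  bf <- signal::butter(spec$order, spec$band / nyq, type = "pass")
  apply_f <- if (spec$zero_phase) {
    function(x) signal::filtfilt(bf, x)
  } else {
    function(x) as.numeric(signal::filter(bf, x))
  }
  for (i in seq_len(nrow(epochs$data))) {
    x <- epochs$data[i, ]
    epochs$data[i, ] <- apply_f(x - mean(x))
  }
  epochs
}

#' Baseline-correct the epochs
#'
#' Subtracts from every sample the mean of the 200 ms pre-stimulus window
#' (times < 0).
#'
#' @param epochs An `epoch_set` whose window includes -200..0 ms.
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs) {
  check_epochs(epochs)
  base_idx <- which(epochs$times_ms < 0)
  if (length(base_idx) == 0L)
    stop("epoch window does not include a pre-stimulus baseline")
  bl <- rowMeans(epochs$data[, base_idx, drop = FALSE])
  epochs$data <- epochs$data - bl
  epochs
}

#' Flag artifact epochs by amplitude threshold
#'
#' Epochs containing any sample exceeding +/- `threshold` uV are flagged as
#' artifacts (`meta$rejected`), to be excluded from averaging. Intended to
#' run after filtering and baseline correction (the default pipeline
#' order), which is when the threshold is interpretable.
#'
#' @param epochs An `epoch_set`.
#' @param threshold Rejection threshold in uV (> 0); default 80.
#' @return The `epoch_set` with logical `meta$rejected`.
#' @export
reject_artifacts <- function(epochs, threshold = 80) {
  check_epochs(epochs)
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  if (threshold <= 0) stop("threshold must be > 0")
  epochs$meta$rejected <- apply(abs(epochs$data) > threshold, 1L, any)
  epochs
}

exposure_blocks <- function() {
  list(`1` = c(1L, 40L), `2` = c(41L, 80L), `3` = c(81L, 120L))
}

#' Average epochs per condition cell and exposure block
#'
#' Averages retained epochs within each condition cell and exposure block
#' (condition-level exposures 1-40, 41-80, 81-120). A (cell, block) group
#' whose epochs were all rejected is reported with `n_included = 0` and an
#' `NA` waveform rather than dropped.
#'
#' @param epochs An `epoch_set` carrying `meta$rejected` (see
#'   [reject_artifacts()]; if absent, all epochs are retained).
#' @return List of `erp_average` objects, each with `cell`, `block`
#'   (integer 1-3), `waveform`, `times_ms`, `srate`, `sound_onset_ms`,
#'   `n_included`, `n_rejected`.
#' @export
block_average <- function(epochs) {
  check_epochs(epochs)
  rejected <- epochs$meta$rejected
  if (is.null(rejected)) rejected <- rep(FALSE, nrow(epochs$data))
  out <- list()
  for (cell in sort(unique(epochs$meta$cell))) {
    for (b in names(exposure_blocks())) {
      rng <- exposure_blocks()[[b]]
      in_group <- epochs$meta$cell == cell &
        epochs$meta$exposure_idx >= rng[1] & epochs$meta$exposure_idx <= rng[2]
      keep <- in_group & !rejected
      wav <- if (any(keep)) {
        colMeans(epochs$data[keep, , drop = FALSE])
      } else {
        if (any(in_group))
          warning(sprintf("all epochs rejected in cell %s block %s", cell, b))
        rep(NA_real_, ncol(epochs$data))
      }
      out[[paste0(cell, "_", b)]] <- structure(
        list(cell = cell, block = as.integer(b), waveform = wav,
             times_ms = epochs$times_ms, srate = epochs$srate,
             sound_onset_ms = epochs$sound_onset_ms,
             n_included = sum(keep), n_rejected = sum(in_group & rejected)),
        class = "erp_average")
    }
  }
  out
}

#' Measure the P300-like peak of an averaged waveform
#'
#' Finds the largest positive peak 250-600 ms after sound onset (window
#' edges inclusive) and reports its baseline-to-peak amplitude (the peak
#' value of the baseline-corrected average) and latency. Among tied maxima
#' the earliest sample wins. If the whole window is negative the maximum is
#' still returned, flagged `negative`; a maximum sitting on a window edge
#' is flagged `edge`.
#'
#' @param avg An `erp_average` (or any list with `waveform`, `times_ms`,
#'   `sound_onset_ms`).
#' @param sound_onset_ms Sound-event time within the epoch, ms; defaults to
#'   the value stored in `avg`.
#' @param window Search window relative to sound onset, ms (inclusive).
#' @return An object of class `p300_measure`: `amplitude_uV`, `latency_ms`
#'   (post-sound), `edge`, `negative`, plus the cell/block labels when
#'   present in `avg`.
#' @export
measure_p300 <- function(avg, sound_onset_ms = NULL, window = c(250, 600)) {
  if (!is.list(avg) || is.null(avg$waveform) || is.null(avg$times_ms))
    stop("avg must carry waveform and times_ms")
  if (is.null(sound_onset_ms)) sound_onset_ms <- avg$sound_onset_ms
  stopifnot(is.numeric(sound_onset_ms), length(sound_onset_ms) == 1L)
  t_rel <- avg$times_ms - sound_onset_ms
  idx <- which(t_rel >= window[1] & t_rel <= window[2])
  if (length(idx) == 0L) stop("search window lies outside the epoch")
  w <- avg$waveform[idx]
  if (all(is.na(w)))
    return(structure(list(amplitude_uV = NA_real_, latency_ms = NA_real_,
                          edge = NA, negative = NA, cell = avg$cell,
                          block = avg$block), class = "p300_measure"))
  k <- which.max(w) # earliest among ties
  structure(list(
    amplitude_uV = w[k],
    latency_ms = t_rel[idx[k]],
    edge = k == 1L || k == length(w),
    negative = w[k] <= 0,
    cell = avg$cell, block = avg$block
  ), class = "p300_measure")
}

#' @export
print.p300_measure <- function(x, ...) {
  cat(sprintf("<p300_measure> %.3g uV at +%g ms%s%s\n", x$amplitude_uV,
              x$latency_ms, if (isTRUE(x$edge)) " [edge]" else "",
              if (isTRUE(x$negative)) " [negative]" else ""))
  invisible(x)
}

#' Run the full ERP analysis chain
#'
#' The fixed pipeline order is filter -> baseline correction -> artifact
#' rejection -> block averaging -> P300 peak measurement. Whether the
#' +/- threshold screen is applied before or after filtering is
#' configurable (`reject_before_filter`), defaulting to after, where the
#' threshold applies to the signal actually averaged.
#'
#' @param epochs An `epoch_set` (raw, from [simulate_epochs()] or
#'   [read_epoch_set()]).
#' @param band Pass band in Hz.
#' @param threshold Artifact rejection threshold in uV.
#' @param reject_before_filter Apply the threshold to raw epochs instead of
#'   filtered ones.
#' @return Data frame with one row per (cell, block): `cell`, `block`,
#'   `n_included`, `n_rejected`, `p300_amplitude_uV`, `p300_latency_ms`,
#'   `edge`, `negative`.
#' @export
analyze_experiment <- function(epochs, band = c(0.1, 20), threshold = 80,
                               reject_before_filter = FALSE) {
  check_epochs(epochs)
  if (reject_before_filter) {
    epochs <- reject_artifacts(epochs, threshold)
    epochs <- baseline_correct(bandpass(epochs, filter_spec(band)))
  } else {
    epochs <- baseline_correct(bandpass(epochs, filter_spec(band)))
    epochs <- reject_artifacts(epochs, threshold)
  }
  avgs <- block_average(epochs)
  rows <- lapply(avgs, function(a) {
    m <- measure_p300(a)
    data.frame(cell = a$cell, block = a$block, n_included = a$n_included,
               n_rejected = a$n_rejected, p300_amplitude_uV = m$amplitude_uV,
               p300_latency_ms = m$latency_ms, edge = m$edge,
               negative = m$negative)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Check the qualitative block-amplitude pattern of the 2x2 design
#'
#' Evaluates, on a block-amplitude table from [analyze_experiment()], the
#' qualitative habituation pattern reported for the familiarity-by-
#' congruency experiment: (i) high-uncertainty cells (B*) drop from block 1
#' to block 2 by more than `margin` uV; (ii) low-uncertainty cells (A*)
#' stay within `margin` from block 1 to block 2 but drop from block 1 to
#' block 3; (iii) the block-1 amplitude ordering between uncertainty levels
#' flips with prediction-error level (BX > AX yet AY > BY).
#'
#' @param tab Output of [analyze_experiment()] with the four cells AX, AY,
#'   BX, BY.
#' @param margin Amplitude margin in uV defining a "drop".
#' @return List of logicals `high_drop_block2`, `low_flat_block2`,
#'   `low_drop_block3`, `ordering_flip`, and `all` (their conjunction).
#' @export
erp_pattern_check <- function(tab, margin = 1) {
  amp <- function(cell, block) {
    v <- tab$p300_amplitude_uV[tab$cell == cell & tab$block == block]
    if (length(v) != 1L) stop("table must have one row per (cell, block)")
    v
  }
  high_drop <- all(vapply(c("BX", "BY"), function(cl)
    amp(cl, 1) - amp(cl, 2) > margin, logical(1)))
  low_flat <- all(vapply(c("AX", "AY"), function(cl)
    abs(amp(cl, 1) - amp(cl, 2)) < margin, logical(1)))
  low_drop3 <- all(vapply(c("AX", "AY"), function(cl)
    amp(cl, 1) - amp(cl, 3) > margin, logical(1)))
  flip <- amp("BX", 1) > amp("AX", 1) && amp("AY", 1) > amp("BY", 1)
  list(high_drop_block2 = high_drop, low_flat_block2 = low_flat,
       low_drop_block3 = low_drop3, ordering_flip = flip,
       all = high_drop && low_flat && low_drop3 && flip)
}
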