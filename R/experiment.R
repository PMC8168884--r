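#' Condition cells of the 2x2 familiarity-by-congruency design
#'
#' Maps the four stimulus types of the surprise-habituation experiment onto
#' habituation-model parameters. Instrument familiarity manipulates the
#' initial uncertainty (familiar A = low s_pI, unfamiliar B = high s_pI);
#' audio-visual congruency manipulates the initial prediction error
#' (congruent X = low delta_I, incongruent Y = high delta_I). Noise and
#' learning rate are shared across cells, mirroring the shared stimulus
#' stream.
#'
#' The default mapping (s_pI 1 vs 30, delta_I 0 vs 10, s_l = 0.5,
#' alpha = 0.1) puts the uncertainty pair above the reversal threshold
#' (1 x 30 > 25), so the *cumulative* gain ordering between cells reverses
#' with prediction-error level. Note the instantaneous first-exposure gain
#' does not reverse for this pair at delta_I = 10 (the A-term still
#' dominates); pairs such as (8, 30) reverse instantaneously.
#'
#' @param uncertainty Length-2 numeric `c(low, high)` initial uncertainties.
#' @param prediction_error Length-2 numeric `c(low, high)` prediction
#'   errors.
#' @param noise Shared external noise variance.
#' @param learning_rate Shared learning rate.
#' @return Named list of four [habituation_params()] (`AX`, `AY`, `BX`,
#'   `BY`), class `condition_cells`.
#' @export
condition_cells <- function(uncertainty = c(low = 1, high = 30),
                            prediction_error = c(low = 0, high = 10),
                            noise = 0.5, learning_rate = 0.1) {
  stopifnot(length(uncertainty) == 2L, length(prediction_error) == 2L)
  if (uncertainty[1] >= uncertainty[2])
    stop("uncertainty must be c(low, high) with low < high")
  if (prediction_error[1] >= prediction_error[2])
    stop("prediction_error must be c(low, high) with low < high")
  cells <- list(
    AX = habituation_params(uncertainty[1], prediction_error[1], noise,
                            learning_rate),
    AY = habituation_params(uncertainty[1], prediction_error[2], noise,
                            learning_rate),
    BX = habituation_params(uncertainty[2], prediction_error[1], noise,
                            learning_rate),
    BY = habituation_params(uncertainty[2], prediction_error[2], noise,
                            learning_rate)
  )
  structure(cells, class = "condition_cells")
}

#' Generative configuration for the synthetic experiment
#'
#' Parameters of the linking functions that turn model information gain into
#' observable data: an affine gain-to-amplitude map for the P300-like
#' component, an ordered-threshold (cumulative) model for the 4-level Likert
#' surprise ratings, plus background-noise and artifact settings.
#'
#' Defaults are chosen so that (i) the largest deterministic single-trial
#' amplitude stays well below the 80 uV artifact-rejection threshold, and
#' (ii) a single synthetic subject's 40-trial block averages resolve the
#' model-driven amplitude differences (the background noise is accordingly
#' cleaner than real EEG, where group averaging does that work).
#'
#' @param p300_gain_slope uV of P300-like amplitude per nat of information
#'   gain.
#' @param p300_baseline uV of amplitude at zero gain.
#' @param p300_latency_mean Mean bump latency, ms after sound onset; with
#'   jitter, clamped to `latency_bounds`.
#' @param p300_latency_jitter SD of the per-trial latency jitter, ms.
#' @param latency_bounds Length-2 clamp on latency (ms post-sound); must lie
#'   inside the 250-600 ms measurement window.
#' @param p300_width SD of the Gaussian bump, ms.
#' @param noise_rms RMS amplitude of the background noise, uV.
#' @param noise_model `"pink"` (1/f, band-limited 0.1-40 Hz) or `"white"`
#'   (analytically convenient).
#' @param blink_rate Probability per epoch of an injected blink artifact.
#' @param blink_amplitude Peak amplitude of the blink bump, uV (must exceed
#'   the 80 uV screen so injected blinks are threshold-detectable).
#' @param rating_thresholds Three strictly increasing cutpoints on the gain
#'   scale for the 4-level Likert readout.
#' @param rating_noise_sd SD of the Gaussian noise added to gain before
#'   thresholding.
#' @param seed Integer seed; all simulation randomness derives from it.
#' @return An object of class `generative_config`.
#' @export
generative_config <- function(p300_gain_slope = 25, p300_baseline = 2,
                              p300_latency_mean = 400,
                              p300_latency_jitter = 8,
                              latency_bounds = c(300, 550),
                              p300_width = 45,
                              noise_rms = 4, noise_model = c("pink", "white"),
                              blink_rate = 0.03, blink_amplitude = 150,
                              rating_thresholds = c(0.05, 0.35, 1),
                              rating_noise_sd = 0.08, seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(latency_bounds) == 2L, length(rating_thresholds) == 3L)
  if (latency_bounds[1] < 250 || latency_bounds[2] > 600 ||
      latency_bounds[1] >= latency_bounds[2])
    stop("latency_bounds must be an increasing interval inside [250, 600]")
  if (is.unsorted(rating_thresholds, strictly = TRUE))
    stop("rating_thresholds must be strictly increasing")
  if (blink_rate < 0 || blink_rate > 1) stop("blink_rate must be in [0, 1]")
  if (noise_rms < 0) stop("noise_rms must be >= 0")
  structure(list(p300_gain_slope = p300_gain_slope,
                 p300_baseline = p300_baseline,
                 p300_latency_mean = p300_latency_mean,
                 p300_latency_jitter = p300_latency_jitter,
                 latency_bounds = latency_bounds,
                 p300_width = p300_width,
                 noise_rms = noise_rms, noise_model = noise_model,
                 blink_rate = blink_rate, blink_amplitude = blink_amplitude,
                 rating_thresholds = rating_thresholds,
                 rating_noise_sd = rating_noise_sd,
                 seed = as.integer(seed)),
            class = "generative_config")
}

## cell membership of the eight stimulus ids (two videos per cell)
stimulus_cell_map <- function() {
  c("AX", "AX", "AY", "AY", "BX", "BX", "BY", "BY")
}

#' Build the randomized trial schedule
#'
#' 480 trials: 8 videos (2 per condition cell) x 60 presentation sets, each
#' set a fresh random permutation of the 8 videos. Inter-trial intervals are
#' uniform on \[1000, 2000\] ms. Surprise ratings are probed during sets 1,
#' 20, 40 and 60. The condition-level exposure index counts presentations
#' within a cell (2 per set, reaching 120), the index that drives the model
#' gain.
#'
#' @param seed Integer seed; identical seeds give identical schedules.
#' @return A `trial_log`: data frame with columns `trial`, `set`,
#'   `trial_in_set`, `stimulus_id`, `cell`, `exposure_idx`, `iti_ms`,
#'   `probe`, `rating` (all `NA` until [simulate_ratings()]).
#' @export
build_schedule <- function(seed = 1L) {
  set.seed(as.integer(seed))
  cells <- stimulus_cell_map()
  probe_sets <- c(1L, 20L, 40L, 60L)
  counts <- c(AX = 0L, AY = 0L, BX = 0L, BY = 0L)
  rows <- vector("list", 60L)
  for (s in seq_len(60L)) {
    order_s <- sample.int(8L)
    cell_s <- cells[order_s]
    expo <- integer(8L)
    for (k in seq_len(8L)) {
      counts[cell_s[k]] <- counts[cell_s[k]] + 1L
      expo[k] <- counts[cell_s[k]]
    }
    rows[[s]] <- data.frame(
      set = s, trial_in_set = seq_len(8L), stimulus_id = order_s,
      cell = cell_s, exposure_idx = expo,
      iti_ms = stats::runif(8L, 1000, 2000),
      probe = s %in% probe_sets, rating = NA_integer_
    )
  }
  log <- do.call(rbind, rows)
  log <- cbind(trial = seq_len(nrow(log)), log)
  rownames(log) <- NULL
  class(log) <- c("trial_log", "data.frame")
  log
}

#' Simulate Likert surprise ratings
#'
#' Fills in the 4-level ratings on probe trials via an ordered-threshold
#' readout of the model: the information gain of that trial's cell at its
#' exposure index, plus Gaussian noise, cut at the three configured
#' thresholds. Expected ratings therefore decay with exposure exactly as the
#' gain curves do.
#'
#' @param log A `trial_log` from [build_schedule()].
#' @param cells A [condition_cells()].
#' @param cfg A [generative_config()]; `cfg$seed` drives the rating noise.
#' @return The `trial_log` with `rating` set on probe trials.
#' @export
simulate_ratings <- function(log, cells, cfg) {
  stopifnot(inherits(log, "trial_log"), inherits(cfg, "generative_config"))
  if (!inherits(cells, "condition_cells"))
    stop("cells must be a condition_cells mapping")
  if (!all(unique(log$cell) %in% names(cells)))
    stop("trial log contains cells missing from the condition mapping")
  set.seed(cfg$seed + 1L)
  idx <- which(log$probe)
  g <- vapply(idx, function(i)
    information_gain(cells[[log$cell[i]]], log$exposure_idx[i]), numeric(1))
  latent <- g + stats::rnorm(length(idx), 0, cfg$rating_noise_sd)
  log$rating[idx] <- 1L + findInterval(latent, cfg$rating_thresholds)
  log
}

## band-limited 1/f noise, exact RMS; n samples at fs Hz
pink_noise <- function(n, rms, fs, f_lo = 0.1, f_hi = 40) {
  if (rms == 0) return(numeric(n))
  nf <- (n - 1L) %/% 2L
  f <- seq_len(nf) * fs / n
  amp <- ifelse(f >= f_lo & f <= f_hi, 1 / sqrt(f), 0)
  spec <- complex(modulus = amp,
                  argument = stats::runif(nf, 0, 2 * pi))
  full <- if (n %% 2L == 0L) {
    c(0, spec, 0, Conj(rev(spec)))
  } else {
    c(0, spec, Conj(rev(spec)))
  }
  x <- Re(stats::fft(full, inverse = TRUE))
  s <- sqrt(mean(x^2))
  if (s == 0) numeric(n) else x * rms / s
}

gaussian_bump <- function(times_ms, center_ms, sd_ms, amplitude) {
  amplitude * exp(-((times_ms - center_ms)^2) / (2 * sd_ms^2))
}

#' Simulate synthetic EEG epochs with a habituating P300-like component
#'
#' One 1700-sample epoch (1000 Hz, -200..+1499 ms around video onset; sound
#' at +500 ms) per trial, at a single parietal channel: background noise
#' plus a positive Gaussian bump at the configured post-sound latency whose
#' amplitude is `p300_baseline + p300_gain_slope * G_n`, with G_n the
#' information gain of the trial's cell at its exposure index. Blink
#' artifacts exceeding the 80 uV screen are injected with probability
#' `blink_rate`. Fully reproducible from `cfg$seed`.
#'
#' @inheritParams simulate_ratings
#' @return An `epoch_set`: list with `data` (trials x samples matrix, uV),
#'   `times_ms`, `srate`, `sound_onset_ms`, `channel`, and `meta` (the trial
#'   log plus per-epoch `injected_gain`, `injected_amplitude_uV`,
#'   `injected_latency_ms` post-sound, `blink`).
#' @export
simulate_epochs <- function(log, cells, cfg) {
  stopifnot(inherits(log, "trial_log"), inherits(cfg, "generative_config"))
  if (!inherits(cells, "condition_cells"))
    stop("cells must be a condition_cells mapping")
  if (!all(unique(log$cell) %in% names(cells)))
    stop("trial log contains cells missing from the condition mapping")
  set.seed(cfg$seed + 2L)
  srate <- 1000
  times <- seq(-200L, 1499L)
  n_t <- length(times)
  n_trial <- nrow(log)
  sound <- 500

  gain <- numeric(n_trial)
  for (cell in names(cells)) {
    i <- log$cell == cell
    gain[i] <- information_gain(cells[[cell]], log$exposure_idx[i])
  }
  amplitude <- cfg$p300_baseline + cfg$p300_gain_slope * gain
  latency <- round(pmin(pmax(
    stats::rnorm(n_trial, cfg$p300_latency_mean, cfg$p300_latency_jitter),
    cfg$latency_bounds[1]), cfg$latency_bounds[2]))
  blink <- stats::runif(n_trial) < cfg$blink_rate
  blink_center <- stats::runif(n_trial, -100, 1400)
  blink_sign <- sample(c(-1, 1), n_trial, replace = TRUE)

  data <- matrix(0, n_trial, n_t)
  for (i in seq_len(n_trial)) {
    x <- switch(cfg$noise_model,
                pink = pink_noise(n_t, cfg$noise_rms, srate),
                white = stats::rnorm(n_t, 0, cfg$noise_rms))
    x <- x + gaussian_bump(times, sound + latency[i], cfg$p300_width,
                           amplitude[i])
    if (blink[i])
      x <- x + gaussian_bump(times, blink_center[i], 60,
                             blink_sign[i] * cfg$blink_amplitude)
    data[i, ] <- x
  }
  meta <- as.data.frame(log)
  meta$injected_gain <- gain
  meta$injected_amplitude_uV <- amplitude
  meta$injected_latency_ms <- latency
  meta$blink <- blink
  structure(list(data = data, times_ms = times, srate = srate,
                 sound_onset_ms = sound, channel = "Pz", meta = meta),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d epochs x %d samples @ %g Hz, channel %s, sound at +%g ms\n",
    nrow(x$data), ncol(x$data), x$srate, x$channel, x$sound_onset_ms))
  invisible(x)
}

#' Simulate a complete synthetic subject
#'
#' Convenience wrapper: schedule, ratings and epochs from one seed.
#'
#' @param seed Integer seed for schedule and simulations.
#' @param cells A [condition_cells()] (defaults to the standard mapping).
#' @param cfg A [generative_config()]; its seed is replaced by `seed`.
#' @return List with `log` (rated trial log) and `epochs` (an `epoch_set`).
#' @export
simulate_subject <- function(seed = 1L, cells = condition_cells(),
                             cfg = generative_config()) {
  cfg$seed <- as.integer(seed)
  log <- build_schedule(seed)
  log <- simulate_ratings(log, cells, cfg)
  list(log = log, epochs = simulate_epochs(log, cells, cfg))
}
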