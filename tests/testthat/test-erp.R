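# minimal epoch container for unit contracts (two cells x 3 blocks
# worth of metadata only when needed)
make_epochs <- function(data, cell = rep("AX", nrow(data)),
                        exposure = seq_len(nrow(data))) {
  structure(list(
    data = data, times_ms = seq(-200L, 1499L), srate = 1000,
    sound_onset_ms = 500, channel = "Pz",
    meta = data.frame(trial = seq_len(nrow(data)), cell = cell,
                      exposure_idx = exposure)
  ), class = "epoch_set")
}

test_that("band-pass attenuates stop band and preserves pass band", {
  t <- seq(-200, 1499) / 1000
  ep <- make_epochs(rbind(sin(2 * pi * 50 * t), sin(2 * pi * 5 * t), 0 * t))
  out <- bandpass(ep, filter_spec(c(0.1, 20)))
  mid <- 300:1400 # avoid filtfilt edge transients
  expect_lt(max(abs(out$data[1, mid])), 10^(-20 / 20)) # >= 20 dB down at 50 Hz
  expect_equal(max(abs(out$data[2, mid])), 1, tolerance = 0.05) # 5 Hz kept
  expect_equal(out$data[3, ], rep(0, 1700)) # linearity: zero in, zero out
  expect_identical(out$meta, ep$meta)
})

test_that("band edges above Nyquist are refused", {
  ep <- make_epochs(matrix(0, 1, 1700))
  expect_error(bandpass(ep, filter_spec(c(0.1, 600))), "Nyquist")
  expect_error(filter_spec(c(5, 1)), "band")
})

test_that("baseline correction subtracts the pre-stimulus mean", {
  const <- matrix(7, 2, 1700)
  expect_equal(baseline_correct(make_epochs(const))$data,
               matrix(0, 2, 1700))
  # already-zero baseline: unchanged
  step <- matrix(0, 1, 1700); step[1, 201:1700] <- 5
  out <- baseline_correct(make_epochs(step))
  expect_equal(out$data, step)
  expect_equal(out$data[1, 1:200], rep(0, 200))
  expect_equal(out$data[1, 300], 5)
})

test_that("threshold rule flags exactly the epochs that exceed it", {
  d <- matrix(0, 3, 1700)
  d[1, 700] <- 79.9   # below threshold: retained
  d[2, 700] <- 100    # synthetic blink: rejected
  d[3, 900] <- -81    # negative excursions count too
  out <- reject_artifacts(make_epochs(d), 80)
  expect_identical(out$meta$rejected, c(FALSE, TRUE, TRUE))
  expect_error(reject_artifacts(make_epochs(d), -1), "> 0")
})

test_that("a blink on every trial rejects the whole recording", {
  cfg <- generative_config(blink_rate = 1, seed = 11)
  ep <- simulate_epochs(build_schedule(11), condition_cells(), cfg)
  ep <- reject_artifacts(baseline_correct(bandpass(ep)), 80)
  expect_true(all(ep$meta$rejected))
  w <- capture_warnings(block_average(ep))
  expect_true(any(grepl("all epochs rejected", w)))
})

test_that("block averaging is an arithmetic mean with conserved counts", {
  wave <- sin(seq(-200, 1499) / 40)
  d <- rbind(wave, wave, wave, -wave)
  ep <- make_epochs(d, cell = rep("AX", 4), exposure = c(1, 2, 41, 42))
  ep$meta$rejected <- c(FALSE, FALSE, FALSE, FALSE)
  avgs <- block_average(ep)
  expect_equal(avgs[["AX_1"]]$waveform, wave) # idempotent on identical epochs
  expect_equal(avgs[["AX_2"]]$waveform, rep(0, 1700)) # +v, -v cancel
  expect_equal(avgs[["AX_1"]]$n_included, 2)
  expect_equal(avgs[["AX_3"]]$n_included, 0)
  # rejected epochs are excluded and counted
  ep$meta$rejected <- c(FALSE, TRUE, FALSE, FALSE)
  avgs <- suppressWarnings(block_average(ep))
  expect_equal(avgs[["AX_1"]]$n_included, 1)
  expect_equal(avgs[["AX_1"]]$n_rejected, 1)
})

test_that("peak measurement returns the injected bump exactly, with tie and edge rules", {
  times <- seq(-200L, 1499L)
  wav <- 7 * exp(-((times - 850)^2) / (2 * 45^2)) # 350 ms post-sound
  avg <- list(waveform = wav, times_ms = times, sound_onset_ms = 500)
  m <- measure_p300(avg)
  expect_equal(m$amplitude_uV, 7)
  expect_equal(m$latency_ms, 350)
  expect_false(m$edge); expect_false(m$negative)

  # two equal maxima: earliest wins
  wav2 <- rep(0, 1700); wav2[times == 800] <- 3; wav2[times == 1000] <- 3
  m2 <- measure_p300(list(waveform = wav2, times_ms = times,
                          sound_onset_ms = 500))
  expect_equal(m2$latency_ms, 300)

  # an all-negative window is still measured but flagged
  m3 <- measure_p300(list(waveform = rep(-1, 1700), times_ms = times,
                          sound_onset_ms = 500))
  expect_true(m3$negative)
  expect_true(m3$edge) # constant window: max sits on the first sample
  expect_equal(m3$amplitude_uV, -1)
})

test_that("full pipeline recovers noise-free block amplitudes and their ordering", {
  cfg <- generative_config(noise_rms = 0, blink_rate = 0,
                           p300_latency_jitter = 0, seed = 21)
  ep <- simulate_epochs(build_schedule(21), condition_cells(), cfg)
  tab <- analyze_experiment(ep)
  m <- ep$meta
  for (k in seq_len(nrow(tab))) {
    i <- m$cell == tab$cell[k] &
      m$exposure_idx > (tab$block[k] - 1) * 40 &
      m$exposure_idx <= tab$block[k] * 40
    injected <- mean(m$injected_amplitude_uV[i])
    # zero-phase filtering shaves a few percent off the bump
    expect_equal(tab$p300_amplitude_uV[k], injected, tolerance = 0.08)
  }
  amp <- function(cl, b) tab$p300_amplitude_uV[tab$cell == cl & tab$block == b]
  # cumulative-gain ordering flip across prediction-error levels at block 1
  expect_gt(amp("BX", 1), amp("AX", 1))
  expect_gt(amp("AY", 1), amp("BY", 1))
  # high-uncertainty cells decay from block 1 to block 2
  expect_gt(amp("BY", 1) - amp("BY", 2), 1)
  expect_gt(amp("BX", 1) - amp("BX", 2), 0.2)
})

test_that("pipeline is deterministic and the screen order option changes only flags", {
  cfg <- generative_config(seed = 31)
  ep <- simulate_epochs(build_schedule(31), condition_cells(), cfg)
  t1 <- analyze_experiment(ep)
  t2 <- analyze_experiment(ep)
  expect_identical(t1, t2)
  t3 <- analyze_experiment(ep, reject_before_filter = TRUE)
  expect_identical(names(t3), names(t1))
  expect_equal(sum(t3$n_included + t3$n_rejected),
               sum(t1$n_included + t1$n_rejected))
})

test_that("noisy single subjects still show the dominant ordering effects on average", {
  seeds <- 101:112
  stats <- sapply(seeds, function(s) {
    tab <- analyze_experiment(simulate_subject(s)$epochs)
    amp <- function(cl, b)
      tab$p300_amplitude_uV[tab$cell == cl & tab$block == b]
    c(yflip = amp("AY", 1) - amp("BY", 1),
      bydrop = amp("BY", 1) - amp("BY", 3),
      aydrop = amp("AY", 1) - amp("AY", 2))
  })
  expect_gt(mean(stats["yflip", ]), 0.75)   # incongruent flip, ~1.8 uV true
  expect_gt(mean(stats["bydrop", ]), 0.25)  # high-uncertainty habituation
  expect_gt(mean(stats["aydrop", ]), 1.5)   # low-uncertainty cell also decays
  expect_gt(mean(stats["yflip", ] > 0), 0.8)
})

test_that("measured block amplitudes regress on injected gain with the configured slope", {
  # the linking-hypothesis recovery check: across many subjects, measured
  # (cell, block) amplitudes against injected block-mean gains
  n_subj <- 200
  cells <- condition_cells()
  cfg <- generative_config()
  inj <- NULL; meas <- NULL
  for (s in seq_len(n_subj)) {
    sub_log <- build_schedule(s)
    cfg$seed <- s
    ep <- simulate_epochs(sub_log, cells, cfg)
    tab <- analyze_experiment(ep)
    m <- ep$meta
    for (k in seq_len(nrow(tab))) {
      i <- m$cell == tab$cell[k] &
        m$exposure_idx > (tab$block[k] - 1) * 40 &
        m$exposure_idx <= tab$block[k] * 40
      inj <- c(inj, mean(m$injected_gain[i]))
      meas <- c(meas, tab$p300_amplitude_uV[k])
    }
  }
  slope <- stats::coef(stats::lm(meas ~ inj))[2]
  expect_equal(unname(slope), cfg$p300_gain_slope, tolerance = 0.1)
})
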