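make_recording <- function(x_list, fs = 250, ann = NULL) {
  labels <- names(x_list)
  samples <- do.call(rbind, x_list)
  if (is.null(ann)) {
    ann <- data.frame(start = 0, end = length(x_list[[1]]) / fs,
                      task = "resting")
  }
  eeg_recording(samples, fs, labels, ann, subject_id = "t")
}

test_that("notch filter kills line noise and spares the pass-band", {
  fs <- 1000
  t <- (0:(20 * fs - 1)) / fs
  line <- make_recording(list(Fz = sin(2 * pi * 60 * t)), fs)
  out <- notch_filter(line, 60)
  expect_lt(stats::sd(out$samples[1, ]) / stats::sd(line$samples[1, ]), 0.10)

  tone <- make_recording(list(Fz = sin(2 * pi * 10 * t)), fs)
  out10 <- notch_filter(tone, 60)
  expect_equal(stats::sd(out10$samples[1, ]) / stats::sd(tone$samples[1, ]), 1,
               tolerance = 0.01)
  # +-5 Hz away: < 1 dB
  tone55 <- make_recording(list(Fz = sin(2 * pi * 55 * t)), fs)
  out55 <- notch_filter(tone55, 60)
  ratio <- stats::sd(out55$samples[1, ]) / stats::sd(tone55$samples[1, ])
  expect_gt(20 * log10(ratio), -1)

  zero <- make_recording(list(Fz = numeric(5 * fs)), fs)
  expect_equal(max(abs(notch_filter(zero)$samples)), 0)
  expect_error(notch_filter(make_recording(list(Fz = numeric(500)), fs = 100)),
               "Nyquist")
})

test_that("band-pass filter meets its pass- and stop-band contracts", {
  fs <- 1000
  t <- (0:(30 * fs - 1)) / fs
  mid <- (10 * fs):(20 * fs)
  ratio_for <- function(freq) {
    rec <- make_recording(list(Fz = sin(2 * pi * freq * t)), fs)
    out <- bandpass_filter(rec)
    stats::sd(out$samples[1, mid]) / stats::sd(rec$samples[1, mid])
  }
  expect_lt(ratio_for(100), 0.10)           # far stop-band
  expect_lt(20 * log10(ratio_for(54)), -20) # high + 10 Hz
  expect_lt(20 * log10(ratio_for(0.25)), -20) # low / 2
  expect_equal(ratio_for(10), 1, tolerance = 0.05)

  dc <- make_recording(list(Fz = rep(50, 10 * fs)), fs)
  expect_lt(max(abs(mean(bandpass_filter(dc)$samples[1, ]))), 1)

  expect_error(bandpass_filter(make_recording(list(Fz = numeric(2500))),
                               low = 44, high = 0.5),
               "low < high")
})

test_that("filtering is linear", {
  fs <- 250
  set.seed(8)
  x <- stats::rnorm(10 * fs)
  y <- stats::rnorm(10 * fs)
  a <- 2.5; b <- -1.25
  fx <- bandpass_filter(make_recording(list(Fz = x), fs))$samples[1, ]
  fy <- bandpass_filter(make_recording(list(Fz = y), fs))$samples[1, ]
  fxy <- bandpass_filter(make_recording(list(Fz = a * x + b * y), fs))$samples[1, ]
  expect_equal(fxy, a * fx + b * fy, tolerance = 1e-8)
})

test_that("artifact regression removes exact linear contamination", {
  fs <- 250
  set.seed(3)
  n <- 30 * fs
  t <- (0:(n - 1)) / fs
  clean <- sin(2 * pi * 10 * t)
  veog <- generate_band_component("delta", 30, 4, fs, seed = 10)
  emg <- numeric(n)
  rec <- make_recording(
    list(Fz = clean + 0.1 * veog, C1 = clean, C2 = clean, T7 = clean,
         T8 = clean, Oz = clean, VEOG = veog, EMG = emg), fs)
  out <- remove_artifacts(rec)
  expect_false("VEOG" %in% out$channel_labels)
  expect_true(!is.null(out$references))
  err <- sqrt(mean((out$samples["Fz", ] - clean)^2)) / sqrt(mean(clean^2))
  expect_lt(err, 1e-6)

  # regression never inflates variance under additive contamination
  expect_lte(stats::var(out$samples["Fz", ]), stats::var(rec$samples["Fz", ]))
})

test_that("orthogonal references leave channels untouched", {
  fs <- 250
  n <- 10 * fs
  t <- (0:(n - 1)) / fs
  clean <- sin(2 * pi * 10 * t)
  veog <- cos(2 * pi * 10 * t)  # exactly orthogonal over whole periods
  rec <- make_recording(
    list(Fz = clean, C1 = clean, C2 = clean, T7 = clean, T8 = clean,
         Oz = clean, VEOG = veog, EMG = numeric(n)), fs)
  out <- remove_artifacts(rec)
  expect_equal(out$samples["Fz", ], clean, tolerance = 1e-9)
})

test_that("missing reference channels raise a named error", {
  fs <- 250
  rec <- make_recording(list(Fz = numeric(10 * fs), C1 = numeric(10 * fs),
                             C2 = numeric(10 * fs), T7 = numeric(10 * fs),
                             T8 = numeric(10 * fs), Oz = numeric(10 * fs)),
                        fs)
  expect_error(remove_artifacts(rec), "VEOG")
})

test_that("blink removal restores the artifact-free delta power", {
  base <- function(blinks, seed) {
    cohort_spec(n_stroke = 1, n_control = 1, sampling_rate = 250,
                task_sequence = data.frame(task = "resting", duration = 60),
                blink_rate = blinks, emg_burst_rate = 0, seed = seed)
  }
  delta_fz <- function(rec, clean_refs) {
    rec2 <- if (clean_refs) remove_artifacts(rec) else rec
    eps <- epoch_recording(rec2)
    mean(vapply(eps, function(e) {
      band_power(welch_psd(e), "delta")[["Fz"]]
    }, numeric(1)))
  }
  contaminated <- generate_subject(base(12, 77), "control", 1)
  pristine <- generate_subject(base(0, 77), "control", 1)
  # same substream seed: the scalp EEG realization is identical, only the
  # blink train differs, so the artifact-free generation is the oracle
  p_oracle <- delta_fz(pristine, clean_refs = FALSE)
  p_removed <- delta_fz(contaminated, clean_refs = TRUE)
  p_dirty <- delta_fz(contaminated, clean_refs = FALSE)
  expect_gt(p_dirty / p_oracle, 1.05)  # blinks inflate delta before removal
  expect_equal(p_removed / p_oracle, 1, tolerance = 0.10)
})

test_that("epoching cuts within intervals and discards tails", {
  fs <- 100
  n <- 200 * fs
  chans <- stats::setNames(
    rep(list(numeric(n)), 8),
    c("Fz", "C1", "C2", "T7", "T8", "Oz", "VEOG", "EMG"))
  ann <- data.frame(start = c(0, 60, 100), end = c(60, 85, 130),
                    task = c("resting", "walking", "reading"))
  rec <- make_recording(chans, fs, ann)
  eps <- epoch_recording(rec)
  # 60 s -> 6, 25 s -> 2, 30 s -> 3
  expect_length(eps, 11L)
  expect_true(all(vapply(eps, function(e) ncol(e$samples), 0L) == 10 * fs))
  tasks <- vapply(eps, function(e) e$task_label, "")
  expect_equal(table(tasks)[c("resting", "walking", "reading")],
               c(resting = 6L, walking = 2L, reading = 3L),
               ignore_attr = TRUE)
  lv <- vapply(eps, function(e) e$workload_level, 0L)
  expect_equal(unique(lv[tasks == "reading"]), 3L)
  # only scalp channels are kept
  expect_equal(nrow(eps[[1]]$samples), 6L)

  # interval shorter than one epoch yields none (not an error)
  ann2 <- data.frame(start = 0, end = 5, task = "resting")
  rec2 <- make_recording(chans, fs, ann2)
  expect_length(epoch_recording(rec2), 0L)

  # 4 x 180 s at the protocol scale -> 72 epochs
  spec <- tiny_cohort_spec()
  spec$task_sequence <- default_task_sequence(180)
  spec$sampling_rate <- 100
  rec3 <- generate_subject(spec, "control", 1)
  expect_length(epoch_recording(rec3), 72L)
})

test_that("epoching conserves annotated samples up to discarded tails", {
  spec <- tiny_cohort_spec(seed = 55)
  spec$task_sequence <- data.frame(task = c("resting", "walking"),
                                   duration = c(37, 24))
  rec <- generate_subject(spec, "control", 1)
  eps <- epoch_recording(rec)
  annotated <- sum(rec$annotations$end - rec$annotations$start) *
    rec$sampling_rate
  epoch_samples <- sum(vapply(eps, function(e) ncol(e$samples), 0L))
  expect_lte(epoch_samples, annotated)
  expect_lt(annotated - epoch_samples,
            2 * 10 * rec$sampling_rate)  # < epoch_len deficit per interval
})
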