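#' Per-(group, task) spectral profile
#'
#' A band profile assigns one signal variance (in microvolts squared) to each
#' of the five canonical bands; each scalp channel of a generated recording
#' is the sum of five independent band-limited Gaussian components with
#' these variances.
#'
#' @param delta,theta,alpha,beta,gamma Non-negative band variances (uV^2).
#' @return Named numeric vector of class `band_profile`.
#' @export
band_profile <- function(delta, theta, alpha, beta, gamma) {
  v <- c(delta = delta, theta = theta, alpha = alpha, beta = beta,
         gamma = gamma)
  if (any(!is.finite(v)) || any(v < 0)) stop("band variances must be >= 0")
  structure(v, class = c("band_profile", "numeric"))
}

#' Default per-task band profiles
#'
#' Control-group profiles per task: resting is alpha-dominant (eyes-closed
#' posterior rhythm); motor tasks shift power toward theta and away from
#' alpha/beta; reading mildly suppresses alpha. Magnitudes are in the
#' tens-of-uV^2 range typical of scalp EEG band power. Stroke-group
#' profiles apply the default cohort effect — delta x 1.5 and alpha x 0.7
#' relative to the control profile of the same task — the canonical
#' slow-wave shift after ischemic stroke.
#'
#' @return Named list (one [band_profile()] per task label).
#' @export
default_control_profiles <- function() {
  list(
    resting = band_profile(delta = 20, theta = 10, alpha = 30, beta = 12, gamma = 4),
    walking = band_profile(delta = 21, theta = 14, alpha = 27, beta = 9, gamma = 3),
    working = band_profile(delta = 21, theta = 12, alpha = 24, beta = 9, gamma = 5),
    reading = band_profile(delta = 20, theta = 11, alpha = 28, beta = 11, gamma = 4)
  )
}

#' @rdname default_control_profiles
#' @param delta_gain,alpha_gain Multiplicative stroke effect on the delta
#'   and alpha variances of every task profile.
#' @export
default_stroke_profiles <- function(delta_gain = 1.5, alpha_gain = 0.7) {
  lapply(default_control_profiles(), function(p) {
    band_profile(
      delta = unname(p["delta"]) * delta_gain,
      theta = unname(p["theta"]),
      alpha = unname(p["alpha"]) * alpha_gain,
      beta = unname(p["beta"]),
      gamma = unname(p["gamma"])
    )
  })
}

#' Default task sequence of the acquisition protocol
#'
#' Resting, walking, working, reading, 180 s each (the protocol's two
#' resting blocks and the bottle-moving task collapse onto the four
#' analyzed labels).
#'
#' @param duration Per-task duration in seconds.
#' @return Data.frame with columns `task` and `duration`.
#' @export
default_task_sequence <- function(duration = 180) {
  data.frame(task = task_labels(), duration = duration,
             stringsAsFactors = FALSE)
}

#' Generative specification of a synthetic EEG cohort
#'
#' Bundles everything needed to simulate a labeled stroke/control EEG cohort:
#' group sizes, per-(group, task) band-variance profiles, the hemispheric
#' asymmetry factor applied to the stroke group's right-hemisphere channels,
#' artifact rates, task sequence, sampling rate and the master seed.
#'
#' @param n_stroke,n_control Subject counts (total must be >= 2).
#' @param stroke_profiles,control_profiles Named lists (one
#'   [band_profile()] per task label) for each group.
#' @param asymmetry_factor Non-negative amplitude scaling: stroke-group C2
#'   and T8 are scaled by `1 + asymmetry_factor` relative to C1/T7, so band
#'   power scales by `(1 + asymmetry_factor)^2`.
#' @param blink_rate Eye-blink events per minute on VEOG (0 disables).
#' @param emg_burst_rate Muscle-burst events per minute on EMG (0 disables).
#' @param task_sequence Data.frame `(task, duration)`; durations must each
#'   allow at least two 10-s epochs (>= 20 s).
#' @param sampling_rate Hz.
#' @param seed Integer master seed; per-subject substreams are derived from
#'   it so cohorts are reproducible byte-for-byte.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_stroke = 10, n_control = 10,
                        stroke_profiles = default_stroke_profiles(),
                        control_profiles = default_control_profiles(),
                        asymmetry_factor = 0.3,
                        blink_rate = 12, emg_burst_rate = 6,
                        task_sequence = default_task_sequence(),
                        sampling_rate = 1000, seed = 1L) {
  if (n_stroke < 0 || n_control < 0 || n_stroke + n_control < 2) {
    stop("cohort needs at least two subjects in total")
  }
  task_sequence <- as.data.frame(task_sequence)
  if (!all(c("task", "duration") %in% names(task_sequence))) {
    stop("task_sequence needs columns task, duration")
  }
  bad <- setdiff(task_sequence$task, task_labels())
  if (length(bad)) stop("unknown task label(s): ", paste(bad, collapse = ", "))
  if (any(task_sequence$duration < 20)) {
    stop("each task duration must be >= 20 s (two 10-s epochs)")
  }
  for (profs in list(stroke = stroke_profiles, control = control_profiles)) {
    missing <- setdiff(unique(task_sequence$task), names(profs))
    if (length(missing)) {
      stop("missing band profile for task(s): ", paste(missing, collapse = ", "))
    }
  }
  if (asymmetry_factor < 0) stop("asymmetry_factor must be >= 0")
  if (blink_rate < 0 || emg_burst_rate < 0) stop("artifact rates must be >= 0")
  structure(
    list(
      n_stroke = as.integer(n_stroke), n_control = as.integer(n_control),
      profiles = list(stroke = stroke_profiles, control = control_profiles),
      asymmetry_factor = asymmetry_factor,
      blink_rate = blink_rate, emg_burst_rate = emg_burst_rate,
      task_sequence = task_sequence,
      sampling_rate = sampling_rate,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic EEG cohort spec:", x$n_stroke, "stroke /", x$n_control,
      "control subjects\n")
  cat(sprintf("  fs %g Hz; asymmetry %.2f; blinks %g/min; EMG bursts %g/min; seed %d\n",
              x$sampling_rate, x$asymmetry_factor, x$blink_rate,
              x$emg_burst_rate, x$seed))
  cat("  tasks:", paste(sprintf("%s (%gs)", x$task_sequence$task,
                                x$task_sequence$duration), collapse = ", "), "\n")
  invisible(x)
}

# Run `expr` under a locally seeded RNG, restoring global RNG state after.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Per-subject substream seed from the master seed; exact in double
# arithmetic and kept below 2^31.
subject_seed <- function(master, index) {
  as.integer((abs(as.numeric(master)) * 100003 + 7919 * index) %% 2147483647)
}

#' Generate one band-limited Gaussian component
#'
#' White Gaussian noise confined to a frequency band by FFT masking (an
#' ideal band-pass) and rescaled so its empirical variance equals
#' `variance` exactly. The building block of the synthetic signal model:
#' each scalp channel is the sum of five such components.
#'
#' @param band One-row band definition (see [band_definition()]), or a band
#'   name string.
#' @param duration Seconds (> 0).
#' @param variance Target signal variance (uV^2, >= 0). `0` yields an
#'   all-zero signal.
#' @param sampling_rate Hz; the band must lie inside (0, sampling_rate / 2).
#' @param seed Optional integer; when given, the draw is made under a local
#'   RNG seeded with it (the caller's RNG state is untouched).
#' @return Numeric vector of `duration * sampling_rate` samples.
#' @export
generate_band_component <- function(band, duration, variance, sampling_rate,
                                    seed = NULL) {
  if (is.character(band)) band <- band_definition(band)
  if (duration <= 0) stop("duration must be > 0")
  if (variance < 0) stop("variance must be >= 0")
  if (band$low <= 0 || band$high >= sampling_rate / 2) {
    stop("band [", band$low, ", ", band$high,
         "] Hz outside (0, Nyquist) for fs ", sampling_rate, " Hz")
  }
  n <- round(duration * sampling_rate)
  if (variance == 0) return(numeric(n))
  draw <- function() stats::rnorm(n)
  x <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  # frequency of FFT bin k (0-based) is min(k, n - k) * fs / n
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) * sampling_rate / n
  keep <- freq >= band$low & freq <= band$high
  X <- stats::fft(x)
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(numeric(n))  # degenerate: band captured no bins
  y * sqrt(variance) / s
}

# Biphasic raised-cosine blink pulse (amplitude uV, width s).
blink_pulse <- function(sampling_rate, width = 0.4, amplitude = 100) {
  n <- round(width * sampling_rate)
  t <- seq_len(n) / n
  amplitude * 0.5 * (1 - cos(2 * pi * t)) * sin(2 * pi * t)
}

# Poisson event train: event start times (s) over `duration` at `rate`/min.
poisson_events <- function(rate_per_min, duration) {
  lambda <- rate_per_min / 60 * duration
  n <- stats::rpois(1, lambda)
  if (n == 0) return(numeric(0))
  sort(stats::runif(n, 0, duration))
}

# VEOG channel: biphasic blink pulses at a Poisson rate.
generate_veog <- function(duration, sampling_rate, blink_rate) {
  n <- round(duration * sampling_rate)
  v <- numeric(n)
  if (blink_rate <= 0) return(v)
  pulse <- blink_pulse(sampling_rate)
  for (t0 in poisson_events(blink_rate, duration)) {
    i0 <- floor(t0 * sampling_rate) + 1
    idx <- i0:min(n, i0 + length(pulse) - 1)
    v[idx] <- v[idx] + pulse[seq_along(idx)]
  }
  v
}

# Chin-EMG channel: broadband (> 20 Hz) noise bursts at a Poisson rate.
generate_emg <- function(duration, sampling_rate, burst_rate,
                         burst_width = 0.5, burst_sd = 30) {
  n <- round(duration * sampling_rate)
  v <- numeric(n)
  if (burst_rate <= 0) return(v)
  m <- round(burst_width * sampling_rate)
  env <- 0.5 * (1 - cos(2 * pi * seq_len(m) / m))  # Hann envelope
  high <- min(sampling_rate / 2 * 0.9, 450)
  for (t0 in poisson_events(burst_rate, duration)) {
    noise <- stats::rnorm(m)
    k <- 0:(m - 1)
    freq <- pmin(k, m - k) * sampling_rate / m
    X <- stats::fft(noise)
    X[freq < 20 | freq > high] <- 0
    burst <- Re(stats::fft(X, inverse = TRUE)) / m
    burst <- burst / stats::sd(burst) * burst_sd * env
    i0 <- floor(t0 * sampling_rate) + 1
    idx <- i0:min(n, i0 + m - 1)
    v[idx] <- v[idx] + burst[seq_along(idx)]
  }
  v
}

# Leakage gains of the artifact channels into scalp channels.
artifact_leakage <- function() {
  list(veog = c(Fz = 0.1), emg = c(T7 = 0.1, T8 = 0.1))
}

#' Generate one synthetic subject recording
#'
#' Each scalp channel is a sum of five independent band-limited Gaussian
#' components with variances from the subject's (group, task) profile,
#' generated per task interval. For stroke subjects the right-hemisphere
#' channels C2 and T8 are amplitude-scaled by `1 + asymmetry_factor`
#' (power by its square), emulating the lesioned hemisphere (fixed to the
#' right by convention). VEOG carries biphasic blink pulses that leak into
#' Fz; EMG carries broadband >20 Hz bursts that leak into T7/T8.
#'
#' @param spec A [cohort_spec()].
#' @param group `"stroke"` or `"control"`.
#' @param subject_index Positive integer; combined with the master seed to
#'   derive the subject's RNG substream.
#' @return An [eeg_recording()] with channels Fz, C1, C2, T7, T8, Oz, VEOG,
#'   EMG and annotations matching `spec$task_sequence`.
#' @export
generate_subject <- function(spec, group, subject_index = 1L) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  if (!group %in% c("stroke", "control")) stop("unknown group: ", group)
  fs <- spec$sampling_rate
  mont <- montage_channels()
  scalp <- mont$scalp
  bands <- eeg_bands()
  offset <- if (group == "stroke") 0L else spec$n_stroke
  seed <- subject_seed(spec$seed, offset + subject_index)

  with_local_seed(seed, {
    durations <- spec$task_sequence$duration
    starts <- cumsum(c(0, durations[-length(durations)]))
    total <- sum(durations)
    n_total <- round(total * fs)
    samples <- matrix(0, nrow = length(scalp) + 2, ncol = n_total,
                      dimnames = list(c(scalp, mont$reference), NULL))

    right_gain <- if (group == "stroke") 1 + spec$asymmetry_factor else 1
    gains <- stats::setNames(rep(1, length(scalp)), scalp)
    gains[c("C2", "T8")] <- right_gain

    for (ti in seq_len(nrow(spec$task_sequence))) {
      task <- spec$task_sequence$task[ti]
      prof <- spec$profiles[[group]][[task]]
      idx <- (round(starts[ti] * fs) + 1):round((starts[ti] + durations[ti]) * fs)
      for (ch in scalp) {
        sig <- numeric(length(idx))
        for (bi in seq_len(nrow(bands))) {
          v <- unname(prof[bands$name[bi]])
          sig <- sig + generate_band_component(bands[bi, ], durations[ti], v, fs)
        }
        samples[ch, idx] <- gains[ch] * sig
      }
    }

    veog <- generate_veog(total, fs, spec$blink_rate)
    emg <- generate_emg(total, fs, spec$emg_burst_rate)
    samples["VEOG", ] <- veog
    samples["EMG", ] <- emg
    leak <- artifact_leakage()
    for (ch in names(leak$veog)) {
      samples[ch, ] <- samples[ch, ] + leak$veog[ch] * veog
    }
    for (ch in names(leak$emg)) {
      samples[ch, ] <- samples[ch, ] + leak$emg[ch] * emg
    }

    ann <- data.frame(start = starts, end = starts + durations,
                      task = spec$task_sequence$task,
                      stringsAsFactors = FALSE)
    eeg_recording(samples, fs, rownames(samples), ann, group = group,
                  subject_id = sprintf("%s_%02d", group, subject_index))
  })
}

#' Generate a full synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return List of [eeg_recording()] objects (`n_stroke` stroke then
#'   `n_control` control subjects), fully reproducible from `spec$seed`:
#'   each subject draws from its own RNG substream, so two calls with the
#'   same spec are bit-identical.
#' @export
generate_cohort <- function(spec) {
  stroke <- lapply(seq_len(spec$n_stroke), function(i) {
    generate_subject(spec, "stroke", i)
  })
  control <- lapply(seq_len(spec$n_control), function(i) {
    generate_subject(spec, "control", i)
  })
  c(stroke, control)
}
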