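fv_from_powers <- function(delta, theta, alpha, beta, gamma = 0,
                           channel = "Fz") {
  absp <- matrix(c(delta, theta, alpha, beta, gamma), nrow = 1,
                 dimnames = list(channel,
                                 c("delta", "theta", "alpha", "beta", "gamma")))
  denom <- sum(absp[1, c("delta", "theta", "alpha", "beta")])
  rel <- absp / denom
  structure(list(abs_power = absp, rel_power = rel,
                 channel_labels = channel),
            class = "band_power_vector")
}

test_that("slow-to-fast ratios follow their defining formulas", {
  fv <- fv_from_powers(0.5, 0.1, 0.25, 0.15)
  expect_equal(unname(dar(fv)), 2.0)
  fv2 <- fv_from_powers(0.3, 0.1, 0.3, 0.3)
  expect_equal(unname(dar(fv2)), 1.0)

  fv3 <- fv_from_powers(0.6, 0.2, 0.1, 0.1)
  expect_equal(unname(dtr(fv3)), 3.0)
  expect_equal(unname(dtr(fv_from_powers(0, 0.2, 0.4, 0.4))), 0)

  expect_equal(unname(dtabr(fv_from_powers(1, 1, 1, 1))), 1.0)
  expect_equal(unname(dtabr(fv_from_powers(2, 2, 1, 1))), 2.0)

  # undefined markers on zero denominators
  expect_true(is.na(dar(fv_from_powers(1, 1, 0, 1))))
  expect_true(is.na(dtr(fv_from_powers(1, 0, 1, 1))))
  expect_true(is.na(dtabr(fv_from_powers(1, 1, 0, 0))))

  # ratio consistency: DAR * alpha = delta exactly
  expect_equal(dar(fv) * fv$rel_power[, "alpha"], fv$rel_power[, "delta"],
               ignore_attr = TRUE)
})

test_that("DTABR of a flat four-band PSD matches bandwidth arithmetic", {
  sp <- banded_psd(0.5, 30, channels = "Fz")
  fv <- relative_power(sp)
  expect_equal(unname(dtabr(fv)), (3.5 + 4) / (5 + 17), tolerance = 1e-12)
})

test_that("ratios recover generative variance ratios on simulated data", {
  # delta:alpha 4:1 and delta:theta 2:1 in variance
  prof <- band_profile(delta = 4, theta = 2, alpha = 1, beta = 1, gamma = 0.5)
  spec <- cohort_spec(n_stroke = 1, n_control = 1, sampling_rate = 250,
                      control_profiles = list(resting = prof),
                      stroke_profiles = list(resting = prof),
                      task_sequence = data.frame(task = "resting",
                                                 duration = 300),
                      blink_rate = 0, emg_burst_rate = 0, seed = 17)
  rec <- generate_subject(spec, "control", 1)
  eps <- epoch_recording(rec)
  absm <- Reduce(`+`, lapply(eps, function(e) {
    relative_power(welch_psd(e))$abs_power
  })) / length(eps)
  # recovery is limited by Welch band-edge leakage between bands of very
  # different spectral density (delta loses ~8% below 0.5 Hz; sparse bands
  # gain from their neighbours), so the attainable bound is ~20%
  expect_equal(mean(absm[, "delta"] / absm[, "alpha"]), 4, tolerance = 0.2)
  expect_equal(mean(absm[, "delta"] / absm[, "theta"]), 2, tolerance = 0.2)
  # the ordering and scale of both ratios is always preserved
  expect_gt(mean(absm[, "delta"] / absm[, "alpha"]), 3)
  expect_gt(mean(absm[, "delta"] / absm[, "theta"]), 1.5)
})

test_that("pdBSI satisfies its exact oracle cases and bounds", {
  pairing <- channel_pairing()
  # identical left/right spectra -> 0
  sp <- flat_psd(list(C1 = 1, C2 = 1, T7 = 1, T8 = 1))
  expect_equal(pdbsi(sp, pairing)$overall, 0)

  # right = 3 * left at every bin -> 0.5
  sp3 <- flat_psd(list(C1 = 1, C2 = 3, T7 = 1, T8 = 3))
  b <- pdbsi(sp3, pairing)
  expect_equal(b$overall, 0.5, tolerance = 1e-12)
  expect_equal(unname(b$per_band), rep(0.5, 4), tolerance = 1e-12)

  # random positive spectra always land in [0, 1]
  set.seed(14)
  for (i in 1:200) {
    lv <- as.list(stats::runif(4, 0.1, 10))
    names(lv) <- c("C1", "C2", "T7", "T8")
    sp_r <- flat_psd(lv, shape = function(f) stats::rexp(length(f)) + 1e-6)
    v <- pdbsi(sp_r, pairing)$overall
    expect_gte(v, 0); expect_lte(v, 1)
  }

  # swapping left/right leaves pdBSI unchanged
  swapped <- channel_pairing(list(c("C2", "C1"), c("T8", "T7")))
  sp_a <- flat_psd(list(C1 = 2, C2 = 5, T7 = 1, T8 = 4))
  expect_equal(pdbsi(sp_a, pairing)$overall,
               pdbsi(sp_a, swapped)$overall)

  # scale invariance
  sp_b <- sp_a; sp_b$psd <- sp_a$psd * 7.3
  expect_equal(pdbsi(sp_b, pairing)$overall, pdbsi(sp_a, pairing)$overall)

  # all-zero input: undefined marker
  sp0 <- flat_psd(list(C1 = 0, C2 = 0, T7 = 0, T8 = 0))
  expect_true(is.na(pdbsi(sp0, pairing)$overall))
})

test_that("band asymmetry is signed, bounded and antisymmetric", {
  pairing <- channel_pairing()
  sym <- flat_psd(list(C1 = 2, C2 = 2, T7 = 2, T8 = 2))
  expect_equal(band_asymmetry(sym, pairing, "alpha")$overall, 0)

  # right power 3, left 1 in both pairs -> 0.5
  sp <- flat_psd(list(C1 = 1, C2 = 3, T7 = 1, T8 = 3))
  expect_equal(band_asymmetry(sp, pairing, "alpha")$overall, 0.5,
               tolerance = 1e-12)

  # antisymmetric under left/right swap
  swapped <- channel_pairing(list(c("C2", "C1"), c("T8", "T7")))
  sp_a <- flat_psd(list(C1 = 2, C2 = 5, T7 = 1, T8 = 4))
  expect_equal(band_asymmetry(sp_a, pairing, "delta")$overall,
               -band_asymmetry(sp_a, swapped, "delta")$overall)

  # bounds on random spectra
  set.seed(4)
  for (i in 1:100) {
    lv <- as.list(stats::runif(4, 0, 5))
    names(lv) <- c("C1", "C2", "T7", "T8")
    v <- band_asymmetry(flat_psd(lv), pairing, "theta")$overall
    expect_gte(v, -1); expect_lte(v, 1)
  }

  # zero-sum pairs are excluded; all excluded -> NA
  sp0 <- flat_psd(list(C1 = 0, C2 = 0, T7 = 0, T8 = 0))
  expect_true(is.na(band_asymmetry(sp0, pairing, "alpha")$overall))
})

test_that("asymmetry factor 0.3 maps to the analytic power asymmetry", {
  # amplitude gain 1.3 -> power ratio 1.69 -> (1.69-1)/(1.69+1)
  target <- (1.3^2 - 1) / (1.3^2 + 1)
  expect_equal(target, 0.2565, tolerance = 1e-4)
  spec <- cohort_spec(n_stroke = 1, n_control = 1, sampling_rate = 250,
                      asymmetry_factor = 0.3,
                      task_sequence = data.frame(task = "resting",
                                                 duration = 300),
                      blink_rate = 0, emg_burst_rate = 0, seed = 23)
  rec <- generate_subject(spec, "stroke", 1)
  eps <- epoch_recording(rec)
  est <- mean(vapply(eps, function(e) {
    mean(vapply(eeg_bands()$name[1:4], function(b) {
      band_asymmetry(welch_psd(e), band = b)$overall
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(est, target, tolerance = 0.12)  # single subject, 5 min
})

test_that("increasing asymmetry strictly increases mean pdBSI", {
  levels <- c(0, 0.2, 0.4)
  mean_bsi <- vapply(levels, function(af) {
    mean(vapply(1:20, function(s) {
      spec <- cohort_spec(n_stroke = 1, n_control = 1, sampling_rate = 250,
                          asymmetry_factor = af,
                          task_sequence = data.frame(task = "resting",
                                                     duration = 20),
                          blink_rate = 0, emg_burst_rate = 0,
                          seed = 3000 + s)
      rec <- generate_subject(spec, "stroke", 1)
      eps <- epoch_recording(rec)
      mean(vapply(eps, function(e) pdbsi(welch_psd(e))$overall, numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_bsi) > 0))
})

test_that("feature tables have the advertised shape and ordering", {
  spec <- tiny_cohort_spec(seed = 9)
  coh <- generate_cohort(spec)
  fd <- do.call(rbind, lapply(coh, function(r) {
    extract_features(epoch_recording(r))
  }))
  per_epoch <- build_feature_table(fd, "per-epoch")
  per_task <- build_feature_table(fd, "per-task-mean")

  n_feat <- ncol(per_epoch) - length(meta_columns(per_epoch))
  expect_gt(n_feat, 150)
  # 4 subjects x 4 tasks x 3 epochs (30 s intervals)
  expect_equal(nrow(per_epoch), 4 * 4 * 3)
  expect_equal(nrow(per_task), 4 * 4)

  # column names are machine-parsable scope__feature__band triplets
  feats <- setdiff(names(per_epoch), meta_columns(per_epoch))
  expect_true(all(vapply(strsplit(feats, "__"), length, 0L) == 3L))
  expect_false(anyDuplicated(feats) > 0)

  # one group label per subject
  gl <- tapply(per_epoch$group, per_epoch$subject_id,
               function(g) length(unique(g)))
  expect_true(all(gl == 1))

  # per-task-mean equals the mean of the per-epoch rows
  col <- "Fz__relpow__alpha"
  sub <- per_epoch[per_epoch$subject_id == "stroke_01" &
                     per_epoch$task == "resting", col]
  agg <- per_task[per_task$subject_id == "stroke_01" &
                    per_task$task == "resting", col]
  expect_equal(agg, mean(sub))

  # duplicate epochs are rejected
  expect_error(build_feature_table(rbind(fd, fd[1, ])), "duplicate")
})
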