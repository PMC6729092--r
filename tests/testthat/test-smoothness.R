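test_that("tiling repeats the mean-subtracted segment", {
  set.seed(1)
  x <- rnorm(100)
  xc <- x - mean(x)
  expect_equal(tile_segment(x, 1), xc)
  tiled <- tile_segment(x, 4)
  expect_length(tiled, 400)
  expect_equal(tiled[101:200], xc)
  expect_error(tile_segment(x, 0), class = "sparctug_value_error")
})

test_that("tiling sharpens the spectral peak of a sinusoid", {
  fs <- 100
  t <- (0:199) / fs
  s <- sin(2 * pi * 2 * t)     # integer number of periods
  cfg <- smoothness_config()
  p1 <- normalized_psd(s, fs, cfg)
  p4 <- normalized_psd(tile_segment(s, 4), fs, cfg)
  near_peak <- function(p, lo, hi) mean(p$norm_psd[p$freq > lo & p$freq < hi])
  # off-peak mass shrinks after tiling while the maximum stays 1
  expect_equal(max(p4$norm_psd), 1)
  expect_lt(near_peak(p4, 2.5, 3.5), near_peak(p1, 2.5, 3.5))
})

test_that("normalized PSD locates known spectral structure", {
  fs <- 100
  t <- (0:999) / fs
  p <- normalized_psd(sin(2 * pi * 2 * t), fs)
  expect_equal(max(p$norm_psd), 1)
  expect_true(all(p$norm_psd >= 0 & p$norm_psd <= 1))
  expect_true(all(diff(p$freq) > 0))
  expect_true(all(p$freq > 0 & p$freq <= 10))
  expect_equal(p$freq[which.max(p$norm_psd)], 2, tolerance = 0.05)
  # off-peak mass is negligible for a pure tone
  expect_lt(mean(p$norm_psd[abs(p$freq - 2) > 0.5]), 0.02)

  # stride + step structure: dominant bins at 2 and 4 Hz
  p2 <- normalized_psd(sin(2 * pi * 2 * t) + sin(2 * pi * 4 * t), fs)
  expect_gt(max(p2$norm_psd[abs(p2$freq - 2) < 0.1]), 0.8)
  expect_gt(max(p2$norm_psd[abs(p2$freq - 4) < 0.1]), 0.8)
  expect_lt(max(p2$norm_psd[abs(p2$freq - 2) > 0.3 & abs(p2$freq - 4) > 0.3]), 0.3)

  # white noise spreads comparable power across the band
  set.seed(4)
  pn <- normalized_psd(rnorm(1000), fs)
  expect_gt(sum(pn$norm_psd > 0.2), 30)

  expect_error(normalized_psd(rep(0, 100), fs),
               class = "sparctug_degenerate_spectrum")
  expect_error(normalized_psd(rnorm(5), fs), class = "sparctug_length_error")
})

test_that("SPARC equals the brute-force arc length on constructed profiles", {
  expect_equal(sparc(flat_profile()), -1)
  one <- spike_profile(5)
  expect_equal(sparc(one), arc_length_oracle(one$freq, one$norm_psd),
               tolerance = 1e-9)
  expect_equal(sparc(one), -3, tolerance = 1e-2)
  two <- spike_profile(c(3, 7))
  expect_equal(sparc(two), arc_length_oracle(two$freq, two$norm_psd),
               tolerance = 1e-9)
  expect_equal(sparc(two), -5, tolerance = 1e-2)
  # each added disjoint spike lengthens the curve by ~2
  three <- spike_profile(c(3, 5, 7))
  expect_lt(sparc(three), sparc(two))
  expect_equal(sparc(three) - sparc(two), -2, tolerance = 1e-2)
  expect_error(sparc(tibble::tibble(freq = 1, norm_psd = 1)),
               class = "sparctug_value_error")
})

test_that("discrete SPARC converges under grid refinement", {
  smooth_profile <- function(n) {
    freq <- seq(0, 10, length.out = n)
    tibble::tibble(freq = freq, norm_psd = exp(-(freq - 3)^2 / 2))
  }
  s1 <- sparc(smooth_profile(2001), f_low = 0, f_high = 10)
  s2 <- sparc(smooth_profile(4001), f_low = 0, f_high = 10)
  expect_lt(abs(s1 - s2), 1e-3)
})

test_that("SPARC of a segment is amplitude-invariant and noise-sensitive", {
  fs <- 100
  set.seed(2)
  t <- (0:499) / fs
  clean <- sin(2 * pi * 2 * t) + 0.5 * sin(2 * pi * 4 * t)
  noisy <- clean + rnorm(500, 0, 0.5)
  s_clean <- sparc_of_segment(clean, fs, "phase")
  s_noisy <- sparc_of_segment(noisy, fs, "phase")
  expect_gt(s_clean, s_noisy)          # broadband noise reduces smoothness
  expect_lte(s_clean, -1)
  expect_equal(sparc_of_segment(10 * noisy, fs, "phase"), s_noisy,
               tolerance = 1e-9)
})

test_that("frequency ratio reflects freeze- vs locomotor-band power", {
  # equal band powers constructed at the PSD level give exactly 1
  freq <- seq(0, 10, by = 0.005)
  psd <- numeric(length(freq))
  psd[freq >= 1.5 & freq <= 2.5] <- 2     # locomotor block
  psd[freq >= 5.0 & freq <= 6.0] <- 2     # freeze block, equal integral
  expect_identical(frequency_ratio(tibble::tibble(freq = freq, norm_psd = psd)), 1)

  fs <- 100
  t <- (0:1999) / fs
  expect_lt(frequency_ratio(sin(2 * pi * 2 * t), fs), 0.01)
  # equal-amplitude tones in each band: near-symmetric leakage, FR ~ 1
  fr2 <- frequency_ratio(sin(2 * pi * 2 * t) + sin(2 * pi * 5 * t), fs)
  expect_equal(fr2, 1, tolerance = 0.01)
  # scale invariance
  set.seed(6)
  x <- rnorm(600)
  expect_equal(frequency_ratio(37.5 * x, fs), frequency_ratio(x, fs),
               tolerance = 1e-9)
  expect_error(frequency_ratio(rnorm(50), fs), class = "sparctug_length_error")
  # zero locomotor power is a hard error
  psd0 <- numeric(length(freq))
  psd0[freq >= 5 & freq <= 6] <- 1
  expect_error(frequency_ratio(tibble::tibble(freq = freq, norm_psd = psd0)),
               "locomotor", class = "sparctug_degenerate_spectrum")
})

test_that("analyze_recording yields 48 bounded SPARC values plus FR", {
  tr <- simulate_trial(draw_test_profile("PD", 8), seed = 11, subject_id = "PD08")
  seg <- segment_tug(tr$recording)
  res <- analyze_recording(tr$recording, seg)
  expect_equal(nrow(res), 48)
  expect_true(all(res$sparc <= -1))
  expect_setequal(unique(res$channel),
                  c("acc_l_v", "acc_l_ml", "acc_l_ap", "acc_l_total",
                    "acc_a_v", "acc_a_ml", "acc_a_ap", "acc_a_total"))
  expect_setequal(unique(res$phase),
                  c("sit_to_stand", "walk1", "turn", "walk2",
                    "turn_stand_to_sit", "full"))
  # FR lives on the full-test AP linear acceleration row only
  fr_rows <- res[!is.na(res$fr), ]
  expect_equal(nrow(fr_rows), 1)
  expect_identical(fr_rows$channel, "acc_l_ap")
  expect_identical(fr_rows$phase, "full")
  expect_gte(fr_rows$fr, 0)
  expect_identical(unique(res$subject_id), "PD08")
})

test_that("permuting acceleration axes permutes the per-axis results", {
  tr <- simulate_trial(draw_test_profile("control", 9), seed = 12)
  rec <- tr$recording
  seg <- segment_tug(rec)
  base <- analyze_recording(rec, seg)

  perm <- rec
  perm$acc_v <- rec$acc_ml
  perm$acc_ml <- rec$acc_ap
  perm$acc_ap <- rec$acc_v
  res <- analyze_recording(perm, seg)
  pick <- function(r, ch) r$sparc[r$channel == ch]
  expect_equal(pick(res, "acc_l_v"), pick(base, "acc_l_ml"), tolerance = 1e-10)
  expect_equal(pick(res, "acc_l_ml"), pick(base, "acc_l_ap"), tolerance = 1e-10)
  expect_equal(pick(res, "acc_l_ap"), pick(base, "acc_l_v"), tolerance = 1e-10)
  # the resultant channel is axis-permutation invariant
  expect_equal(pick(res, "acc_l_total"), pick(base, "acc_l_total"),
               tolerance = 1e-10)
})

test_that("trial averaging is an arithmetic mean with metadata checks", {
  make_res <- function(sparc_val, trial) {
    structure(
      tibble::tibble(subject_id = "S1", group = "PD", trial_index = trial,
                     channel = "acc_l_total", phase = "full",
                     sparc = sparc_val, fr = NA_real_),
      class = c("smoothness_result", "tbl_df", "tbl", "data.frame")
    )
  }
  avg <- average_trials(list(make_res(-3, 1L), make_res(-4, 2L), make_res(-5, 3L)))
  expect_equal(avg$sparc, -4)
  expect_equal(avg$n_trials, 3L)
  expect_true(is.na(avg$trial_index))

  same <- average_trials(list(make_res(-2.5, 1L), make_res(-2.5, 2L),
                              make_res(-2.5, 3L)))
  expect_equal(same$sparc, -2.5)

  set.seed(10)
  vals <- rnorm(3, -4)
  rnd <- average_trials(purrr::map2(vals, 1:3, make_res))
  expect_equal(rnd$sparc, mean(vals), tolerance = 1e-12)

  other <- make_res(-3, 1L)
  other$subject_id <- "S2"
  expect_error(average_trials(list(make_res(-3, 1L), other)),
               class = "sparctug_metadata_error")
})
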