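# shared fixtures built in code

# minimal valid recording: quiet gravity baseline plus optional signal columns
make_recording <- function(n = 300, fs = 100, subject_id = "S01",
                           group = "control", trial_index = 1L,
                           acc_ap = NULL, seed = 1) {
  set.seed(seed)
  t <- (0:(n - 1)) / fs
  imu_recording(
    data.frame(
      acc_v = 1 + rnorm(n, 0, 0.01),
      acc_ml = rnorm(n, 0, 0.01),
      acc_ap = acc_ap %||% sin(2 * pi * 2 * t),
      gyro_yaw = rnorm(n, 0, 0.5),
      gyro_pitch = rnorm(n, 0, 0.5),
      gyro_roll = rnorm(n, 0, 0.5)
    ),
    sample_rate = fs, subject_id = subject_id, group = group,
    trial_index = trial_index
  )
}

# cohort profiles drawn as simulate_cohort does, but exposed for direct use
draw_test_profile <- function(group, seed) {
  set.seed(seed)
  subject_profile(
    group,
    spectral_broadening = if (group == "PD") runif(1, 0.15, 0.35)
                          else runif(1, 0.02, 0.08)
  )
}

# constructed spectral profile on an exact [0, 10] Hz grid
flat_profile <- function(n_bins = 1001) {
  structure(
    tibble::tibble(freq = seq(0, 10, length.out = n_bins),
                   norm_psd = rep(1, n_bins)),
    class = c("spectral_profile", "tbl_df", "tbl", "data.frame"),
    f_low = 0, f_high = 10
  )
}

spike_profile <- function(spike_freqs, n_bins = 1001) {
  freq <- seq(0, 10, length.out = n_bins)
  psd <- numeric(n_bins)
  for (f in spike_freqs) psd[which.min(abs(freq - f))] <- 1
  structure(
    tibble::tibble(freq = freq, norm_psd = psd),
    class = c("spectral_profile", "tbl_df", "tbl", "data.frame"),
    f_low = 0, f_high = 10
  )
}

# independent brute-force arc-length oracle: plain loop over bins
arc_length_oracle <- function(freq, psd, f_low = 0, f_high = 10) {
  total <- 0
  for (i in seq_len(length(freq) - 1)) {
    total <- total + sqrt(((freq[i + 1] - freq[i]) / (f_high - f_low))^2 +
                            (psd[i + 1] - psd[i])^2)
  }
  -total
}

# default full-size cohort analysed once and cached across test files
.cohort_cache <- new.env(parent = emptyenv())

analysed_default_cohort <- function(seed = 20260926) {
  key <- as.character(seed)
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  cohort <- simulate_cohort(cohort_spec(seed = seed))
  smooth <- purrr::imap(cohort$trials, function(tr, id) {
    seg <- segment_tug(tr$recording)
    list(smoothness = analyze_recording(tr$recording, seg),
         durations = tug_durations(seg))
  })
  smoothness <- dplyr::bind_rows(purrr::map(smooth, "smoothness"))
  durations <- purrr::imap(smooth, function(s, id) {
    rec <- cohort$trials[[id]]$recording
    dplyr::bind_cols(
      tibble::tibble(subject_id = attr(rec, "subject_id"),
                     group = attr(rec, "group"),
                     trial_index = attr(rec, "trial_index")),
      s$durations
    )
  }) |> dplyr::bind_rows()
  out <- list(cohort = cohort, smoothness = smoothness, durations = durations)
  .cohort_cache[[key]] <- out
  out
}
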