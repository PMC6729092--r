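#' Synthetic TUG subject profile
#'
#' Generative parameters of one simulated subject. The simulator emulates
#' the signal structure the pipeline assumes: oscillatory anteroposterior
#' acceleration with braking/propulsion peaks at the stride (~2 Hz) and step
#' (~4 Hz) harmonics during the walking bouts, an S-curve yaw-rate pulse
#' integrating to about 180 degrees for each of the two turns, bell-shaped
#' pitch excursions at sit-to-stand and stand-to-sit, optional 3–8 Hz
#' freeze-band bursts that locally suppress the locomotor harmonics, and
#' white sensor noise. Control totals default near 9.15 s and PD totals
#' near 14.04 s; walking phases shorten by `trial_speedup` per trial
#' (task learning).
#'
#' Spectral broadening — the PD hallmark of many comparable dominant
#' frequencies instead of two sharp peaks — is produced by slow random
#' frequency jitter and amplitude modulation of the gait harmonics, with
#' `spectral_broadening` the relative bandwidth.
#'
#' @param group `"control"` or `"PD"`.
#' @param phase_durations named numeric of the five phase durations in
#'   seconds (`sit_to_stand`, `walk1`, `turn`, `walk2`, `turn_stand_to_sit`);
#'   defaults sum to 9.15 s (control) or 14.04 s (PD).
#' @param fundamental_hz stride harmonic frequency in Hz (default 2; the
#'   step harmonic sits at twice this).
#' @param harmonic_amp_ap amplitudes in g of the stride and step harmonics
#'   on the AP axis; V and ML are scaled internally.
#' @param spectral_broadening relative bandwidth of the gait harmonics
#'   (default 0.05 control, 0.25 PD).
#' @param freeze_episodes tibble with columns `phase`, `start_offset_s`,
#'   `duration_s`, `intensity_g`; control profiles must have none.
#' @param pitch_excursion_deg peak trunk-pitch excursion at the postural
#'   transitions (default 40).
#' @param yaw_rate_scale multiplies the turn peak yaw rate implied by the
#'   turn duration (default 1; the net turn angle stays ~180 degrees).
#' @param noise_sd accelerometer white-noise SD in g (default 0.02).
#' @param gyro_noise_sd gyroscope white-noise SD in °/s (default 0.5,
#'   typical of the MEMS gyroscopes in wearable IMUs).
#' @param trial_speedup fractional shortening of each walking phase per
#'   successive trial (default 0.04).
#' @return a list of class `subject_profile`.
#' @export
subject_profile <- function(group = c("control", "PD"),
                            phase_durations = NULL,
                            fundamental_hz = 2,
                            harmonic_amp_ap = c(0.25, 0.12),
                            spectral_broadening = NULL,
                            freeze_episodes = NULL,
                            pitch_excursion_deg = 40,
                            yaw_rate_scale = 1,
                            noise_sd = 0.02,
                            gyro_noise_sd = 0.5,
                            trial_speedup = 0.04) {
  group <- match.arg(group)
  if (is.null(phase_durations)) phase_durations <- default_phase_durations(group)
  if (is.null(names(phase_durations))) names(phase_durations) <- tug_phases()
  if (any(phase_durations <= 0)) stop_fmt("spec_error", "phase durations must be positive")
  spectral_broadening <- spectral_broadening %||% if (group == "PD") 0.25 else 0.05
  if (is.null(freeze_episodes)) {
    freeze_episodes <- tibble(phase = character(), start_offset_s = numeric(),
                              duration_s = numeric(), intensity_g = numeric())
  }
  if (group == "control" && nrow(freeze_episodes) > 0) {
    stop_fmt("spec_error", "control profiles cannot have freeze episodes")
  }
  for (i in seq_len(nrow(freeze_episodes))) {
    ph <- freeze_episodes$phase[[i]]
    if (!ph %in% tug_phases()) {
      stop_fmt("spec_error", "freeze episode in unknown phase '", ph, "'")
    }
    if (freeze_episodes$intensity_g[[i]] < 0) {
      stop_fmt("spec_error", "freeze intensity must be >= 0")
    }
    if (freeze_episodes$start_offset_s[[i]] + freeze_episodes$duration_s[[i]] >
        phase_durations[[ph]]) {
      stop_fmt("spec_error", "freeze episode extends past the end of phase '", ph, "'")
    }
  }
  structure(list(group = group, phase_durations = phase_durations,
                 fundamental_hz = fundamental_hz,
                 harmonic_amp_ap = harmonic_amp_ap,
                 spectral_broadening = spectral_broadening,
                 freeze_episodes = freeze_episodes,
                 pitch_excursion_deg = pitch_excursion_deg,
                 yaw_rate_scale = yaw_rate_scale,
                 noise_sd = noise_sd, gyro_noise_sd = gyro_noise_sd,
                 trial_speedup = trial_speedup),
            class = "subject_profile")
}

default_phase_durations <- function(group) {
  if (group == "PD") {
    c(sit_to_stand = 2.00, walk1 = 3.30, turn = 2.80, walk2 = 3.30,
      turn_stand_to_sit = 2.64)  # 14.04 s
  } else {
    c(sit_to_stand = 1.15, walk1 = 2.20, turn = 1.60, walk2 = 2.20,
      turn_stand_to_sit = 2.00)  # 9.15 s
  }
}

# slow unit-variance modulation signal (~0.5 s correlation length)
slow_noise <- function(n, fs) {
  z <- moving_average(rnorm(n), max(2L, round(0.5 * fs)))
  s <- sd(z)
  if (s == 0) return(numeric(n))
  z / s
}

#' Simulate one TUG trial
#'
#' Builds a full six-channel IMU recording for one trial of one subject,
#' together with the exact ground-truth segmentation, at 100 Hz. The
#' recording starts with 1.5 s of quiet sitting (so the onset detector has
#' its noise window) and ends with 1 s of seated rest. Walking-phase
#' durations shrink by the profile's `trial_speedup` per trial index. All
#' randomness flows from `seed`; freeze-episode carriers draw from a
#' sub-stream derived from `seed`, so a zero-intensity episode leaves the
#' recording bit-identical to the episode-free one.
#'
#' @param profile a [subject_profile].
#' @param trial_index trial number 1..3.
#' @param seed integer seed for this trial.
#' @param subject_id label stored in the recording.
#' @param sample_rate sampling rate in Hz (default 100).
#' @return list with elements `recording` (an [imu_recording]) and `truth`
#'   (a ground-truth `tug_segmentation`).
#' @export
simulate_trial <- function(profile, trial_index = 1L, seed = 1L,
                           subject_id = "synthetic", sample_rate = 100) {
  stopifnot(inherits(profile, "subject_profile"))
  fs <- sample_rate
  dur <- profile$phase_durations
  speed <- (1 - profile$trial_speedup)^(trial_index - 1)
  dur[c("walk1", "walk2")] <- dur[c("walk1", "walk2")] * speed

  pre_n <- round(1.5 * fs)
  post_n <- round(1.0 * fs)
  ph_n <- round(dur * fs)
  n <- pre_n + sum(ph_n) + post_n
  starts <- pre_n + c(0, cumsum(ph_n[-5])) + 1L   # 1-based phase starts
  ends <- starts + ph_n                            # half-open ends

  acc_ap <- numeric(n); acc_v <- numeric(n); acc_ml <- numeric(n)
  yaw_rate <- numeric(n); pitch_angle <- numeric(n); roll_rate <- numeric(n)
  sup <- rep(1, n)  # locomotor suppression during freeze episodes
  b <- profile$spectral_broadening
  f0 <- profile$fundamental_hz
  amps <- profile$harmonic_amp_ap

  # freeze bursts first: their randomness lives on a derived sub-stream
  freeze_ap <- numeric(n)
  eps <- profile$freeze_episodes
  for (i in seq_len(nrow(eps))) {
    if (eps$intensity_g[[i]] == 0) next
    ph_idx <- match(eps$phase[[i]], tug_phases())
    s <- starts[[ph_idx]] + round(eps$start_offset_s[[i]] * fs)
    len <- round(eps$duration_s[[i]] * fs)
    idx <- s:(s + len - 1L)
    burst <- with_local_seed(derive_seed(seed, 77777 + i), {
      fc <- runif(1, 4, 7)
      phi <- runif(1, 0, 2 * pi)
      t_ep <- (seq_len(len) - 1) / fs
      eps$intensity_g[[i]] * tukey_window(len, 1) * sin(2 * pi * fc * t_ep + phi)
    })
    freeze_ap[idx] <- freeze_ap[idx] + burst
    sup[idx] <- sup[idx] * (1 - 0.7 * tukey_window(len, 1))
  }

  with_local_seed(derive_seed(seed, trial_index), {
    # oscillatory stepping during walking and (attenuated) turning phases
    gait_scale <- c(sit_to_stand = 0, walk1 = 1, turn = 0.6, walk2 = 1,
                    turn_stand_to_sit = 0.5)
    ratio_v <- c(0.7, 1.1)   # V relatively richer in the step harmonic
    ratio_ml <- c(0.55, 0.3)
    for (p in seq_along(ph_n)) {
      if (gait_scale[[p]] == 0 || ph_n[[p]] < 8) next
      idx <- starts[[p]]:(ends[[p]] - 1L)
      len <- length(idx)
      t_ph <- (seq_len(len) - 1) / fs
      env <- tukey_window(len, 0.3) * gait_scale[[p]] * sup[idx]
      for (k in 1:2) {
        f_inst <- f0 * k * (1 + (b / 2) * slow_noise(len, fs))
        phase <- 2 * pi * cumsum(f_inst) / fs + runif(1, 0, 2 * pi)
        am <- pmax(0.2, 1 + b * slow_noise(len, fs))
        acc_ap[idx] <- acc_ap[idx] + amps[[k]] * env * am * sin(phase)
        acc_v[idx] <- acc_v[idx] +
          amps[[k]] * ratio_v[[k]] * env * am * sin(phase + 0.5 * pi)
        acc_ml[idx] <- acc_ml[idx] +
          amps[[k]] * ratio_ml[[k]] * env * am * sin(phase / ifelse(k == 1, 1, 2) + 0.25 * pi)
      }
      # trunk roll wobble locked to the stride, broadened like the harmonics
      f_roll <- f0 * (1 + (b / 2) * slow_noise(len, fs))
      ph_roll <- 2 * pi * cumsum(f_roll) / fs + runif(1, 0, 2 * pi)
      am_roll <- pmax(0.2, 1 + b * slow_noise(len, fs))
      roll_rate[idx] <- roll_rate[idx] + 14 * env * am_roll *
        (sin(ph_roll) + 0.5 * sin(2 * ph_roll + runif(1, 0, 2 * pi)))
    }

    # parkinsonian 4-6 Hz tremor, scaled by the broadening parameter: this
    # is what spreads the angular channels' spectra and loads the freeze band
    active <- starts[[1]]:(ends[[5]] - 1L)
    n_act <- length(active)
    # irregular tremor: several independent wandering, bursty sub-components
    # spread over 4-7 Hz, so the spectrum gains a raised band of comparable
    # structures rather than one dominant line
    tremor_band <- function() {
      out <- numeric(n_act)
      for (fc in c(4.5, 5.3, 6.2)) {
        ph <- 2 * pi * cumsum(fc * (1 + 0.1 * slow_noise(n_act, fs))) / fs +
          runif(1, 0, 2 * pi)
        am <- pmax(0, 0.6 + slow_noise(n_act, fs))^2
        am <- am / max(mean(am), 1e-12)
        out <- out + am * sin(ph)
      }
      out * tukey_window(n_act, 0.1) / 3
    }
    yaw_rate[active] <- yaw_rate[active] + 25 * b * tremor_band()
    # pitch tremor as the rate of a bounded tremor angle (~b degrees), so the
    # integrated pitch angle carries ripple, not a random walk
    theta_trem <- 0.5 * b * tremor_band()
    pitch_trem <- c(diff(theta_trem), 0) * fs
    roll_rate[active] <- roll_rate[active] + 30 * b * tremor_band()
    acc_ap[active] <- acc_ap[active] + 0.12 * b * tremor_band()
    acc_v[active] <- acc_v[active] + 0.08 * b * tremor_band()
    acc_ml[active] <- acc_ml[active] + 0.08 * b * tremor_band()

    # movement fragmentation: PD transients are decomposed into sub-movements
    # (hesitations at step-like rates), modelled as amplitude ripple on the
    # turn and postural templates, scaled by the broadening parameter
    frag_mod <- function(len) {
      t_f <- (seq_len(len) - 1) / fs
      1 + 0.7 * b * (sin(2 * pi * 1.3 * t_f + runif(1, 0, 2 * pi)) +
                       sin(2 * pi * 2.4 * t_f + runif(1, 0, 2 * pi)))
    }

    # postural bursts on V/AP at sit-to-stand and during sitting down
    burst_at <- function(p, frac0, frac1, amp) {
      i0 <- starts[[p]] + round(frac0 * ph_n[[p]])
      i1 <- starts[[p]] + round(frac1 * ph_n[[p]]) - 1L
      idx <- i0:i1
      len <- length(idx)
      t_b <- (seq_len(len) - 1) / fs
      w <- tukey_window(len, 0.3) * frag_mod(len)
      list(idx = idx, v = amp * w * sin(2 * pi * 1.2 * t_b + 0.6))
    }
    sts <- burst_at(1, 0, 1, 0.35)
    acc_v[sts$idx] <- acc_v[sts$idx] + sts$v
    acc_ap[sts$idx] <- acc_ap[sts$idx] + 0.7 * sts$v
    sit <- burst_at(5, 0.55, 1, 0.30)
    acc_v[sit$idx] <- acc_v[sit$idx] + sit$v
    acc_ap[sit$idx] <- acc_ap[sit$idx] + 0.7 * sit$v

    acc_ap <- acc_ap + freeze_ap
    acc_v <- acc_v + 0.5 * freeze_ap

    # turns: tapered yaw-rate pulses integrating to ~180 degrees each
    yaw_pulse <- function(idx) {
      len <- length(idx)
      w <- tukey_window(len, 0.5)
      peak <- profile$yaw_rate_scale * 180 / (trapz_((seq_len(len) - 1) / fs, w))
      peak * w * frag_mod(len)
    }
    turn1_idx <- starts[[3]]:(ends[[3]] - 1L)
    yaw_rate[turn1_idx] <- yaw_rate[turn1_idx] + yaw_pulse(turn1_idx)
    t2_len <- round(0.6 * ph_n[[5]])
    turn2_idx <- starts[[5]]:(starts[[5]] + t2_len - 1L)
    yaw_rate[turn2_idx] <- yaw_rate[turn2_idx] + yaw_pulse(turn2_idx)

    # trunk pitch: bell excursions over sit-to-stand and the sitting tail
    pitch_bump <- function(idx) {
      profile$pitch_excursion_deg * tukey_window(length(idx), 1) *
        frag_mod(length(idx))
    }
    sts_idx <- starts[[1]]:(ends[[1]] - 1L)
    pitch_angle[sts_idx] <- pitch_angle[sts_idx] + pitch_bump(sts_idx)
    sit_start <- starts[[5]] + round(0.55 * ph_n[[5]])
    sit_idx <- sit_start:(ends[[5]] - 1L)
    pitch_angle[sit_idx] <- pitch_angle[sit_idx] + pitch_bump(sit_idx)
    pitch_rate <- c(diff(pitch_angle), 0) * fs
    pitch_rate[active] <- pitch_rate[active] + pitch_trem

    # the acquisition ranges clip, exactly as the device does
    clip <- function(x, lim) pmin(pmax(x, -lim), lim)
    rec <- imu_recording(
      data.frame(
        acc_v = clip(1 + acc_v + rnorm(n, 0, profile$noise_sd), 8),
        acc_ml = clip(acc_ml + rnorm(n, 0, profile$noise_sd), 8),
        acc_ap = clip(acc_ap + rnorm(n, 0, profile$noise_sd), 8),
        gyro_yaw = clip(yaw_rate + rnorm(n, 0, profile$gyro_noise_sd), 250),
        gyro_pitch = clip(pitch_rate + rnorm(n, 0, profile$gyro_noise_sd), 250),
        gyro_roll = clip(roll_rate + rnorm(n, 0, profile$gyro_noise_sd), 250)
      ),
      sample_rate = fs, subject_id = subject_id, group = profile$group,
      trial_index = trial_index
    )

    truth <- new_tug_segmentation(
      tibble(phase = tug_phases(), start = as.integer(starts),
             end = as.integer(ends), duration_s = ph_n / fs),
      fs, onset = as.integer(starts[[1]]),
      turn2_end = as.integer(starts[[5]] + t2_len)
    )
    list(recording = rec, truth = truth)
  })
}

#' Synthetic cohort specification
#'
#' Group sizes default to the study design the pipeline targets: 31 PD
#' subjects and 6 healthy controls, three trials each (111 recordings). A
#' single seed fixes the entire cohort: subject parameters are drawn under
#' it, and each trial receives a per-trial seed drawn from the same stream.
#'
#' @param n_pd,n_control subjects per group.
#' @param n_trials trials per subject (default 3).
#' @param seed integer cohort seed.
#' @param duration_sd_frac between-subject SD of phase durations, as a
#'   fraction of the group mean (default 0.08).
#' @param broadening_control,broadening_pd ranges of the spectral-broadening
#'   parameter per group.
#' @param freeze_intensity_range intensity range in g of PD freeze bursts.
#' @param max_freeze_episodes most freeze episodes per PD subject (0 to this,
#'   drawn per subject).
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pd = 31L, n_control = 6L, n_trials = 3L, seed = 1L,
                        duration_sd_frac = 0.08,
                        broadening_control = c(0.02, 0.08),
                        broadening_pd = c(0.15, 0.35),
                        freeze_intensity_range = c(0.08, 0.22),
                        max_freeze_episodes = 2L) {
  if (n_pd < 1 || n_control < 1) stop_fmt("spec_error", "need at least one subject per group")
  structure(list(n_pd = as.integer(n_pd), n_control = as.integer(n_control),
                 n_trials = as.integer(n_trials), seed = as.integer(seed),
                 duration_sd_frac = duration_sd_frac,
                 broadening_control = broadening_control,
                 broadening_pd = broadening_pd,
                 freeze_intensity_range = freeze_intensity_range,
                 max_freeze_episodes = as.integer(max_freeze_episodes)),
            class = "cohort_spec")
}

draw_profile <- function(spec, group) {
  base <- default_phase_durations(group)
  durs <- pmax(base * (1 + rnorm(5, 0, spec$duration_sd_frac)), 0.6 * base)
  names(durs) <- tug_phases()
  brange <- if (group == "PD") spec$broadening_pd else spec$broadening_control
  broadening <- runif(1, brange[[1]], brange[[2]])
  eps <- tibble(phase = character(), start_offset_s = numeric(),
                duration_s = numeric(), intensity_g = numeric())
  if (group == "PD" && spec$max_freeze_episodes > 0) {
    n_ep <- sample(0:spec$max_freeze_episodes, 1)
    if (n_ep > 0) {
      phases <- sample(c("turn", "walk1", "turn_stand_to_sit"), n_ep, replace = TRUE)
      eps <- tibble(
        phase = phases,
        start_offset_s = runif(n_ep, 0.05, 0.25) * durs[phases],
        duration_s = pmin(runif(n_ep, 0.6, 1.2), 0.55 * durs[phases]),
        intensity_g = runif(n_ep, spec$freeze_intensity_range[[1]],
                            spec$freeze_intensity_range[[2]])
      )
    }
  }
  subject_profile(group = group, phase_durations = durs,
                  spectral_broadening = broadening, freeze_episodes = eps)
}

clip_score <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)

draw_scores <- function(subject_id, group, degradation) {
  items <- c("speech", "tremor_at_rest", "finger_taps", "alternating_hands",
             "leg_agility", "arising_from_chair", "posture", "gait",
             "postural_stability", "body_bradykinesia")
  item_scores <- clip_score(0.1 + 6.5 * degradation + rnorm(length(items), 0, 0.5), 0, 4)
  out <- as_tibble(as.list(stats::setNames(item_scores, items)))
  dplyr::bind_cols(
    tibble(subject_id = subject_id, group = group, degradation = degradation),
    out,
    tibble(
      updrs_iii = sum(item_scores),
      hy = clip_score(1 + 3.5 * degradation, 1, 5),
      fogq = clip_score(36 * degradation - 1 + rnorm(1, 0, 1.5), 0, 24),
      mmse = clip_score(29 - 6 * degradation + rnorm(1, 0, 1), 20, 30)
    )
  )
}

#' Simulate a full synthetic cohort
#'
#' Draws one [subject_profile] per subject, simulates `n_trials` TUG trials
#' each with ground truth, and co-simulates clinical scores (UPDRS III items
#' and total, H&Y, FOG-Q, MMSE) as monotone linear-plus-noise functions of
#' the subject's smoothness degradation (spectral broadening plus total
#' freeze intensity), clipped to instrument ranges. Greater degradation
#' therefore means higher UPDRS/FOG-Q, higher H&Y, lower MMSE — a known
#' ground-truth association for testing the correlation stage. The whole
#' cohort is a deterministic function of `spec$seed`.
#'
#' @param spec a [cohort_spec].
#' @param write_dir if not `NULL`, recordings are written there in the
#'   canonical text dialect along with `manifest.yaml`.
#' @return a list of class `synthetic_cohort` with elements `manifest`
#'   (tibble: subject, group, trial, per-trial seed, file path if written),
#'   `trials` (named list of `simulate_trial()` outputs), and `scores`
#'   (one row per subject).
#' @export
simulate_cohort <- function(spec = cohort_spec(), write_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- tibble(
    subject_id = c(sprintf("PD%02d", seq_len(spec$n_pd)),
                   sprintf("C%02d", seq_len(spec$n_control))),
    group = c(rep("PD", spec$n_pd), rep("control", spec$n_control))
  )
  res <- with_local_seed(spec$seed, {
    profiles <- purrr::map(subjects$group, function(g) draw_profile(spec, g))
    scores <- purrr::pmap(
      list(subjects$subject_id, subjects$group, profiles),
      function(sid, g, pr) {
        draw_scores(sid, g, pr$spectral_broadening + sum(pr$freeze_episodes$intensity_g))
      }
    )
    trial_seeds <- matrix(
      sample.int(.Machine$integer.max - 1L, nrow(subjects) * spec$n_trials),
      nrow = nrow(subjects)
    )
    list(profiles = profiles, scores = dplyr::bind_rows(scores),
         trial_seeds = trial_seeds)
  })

  manifest <- tidyr::crossing(subjects, trial_index = seq_len(spec$n_trials)) |>
    dplyr::arrange(match(.data$subject_id, subjects$subject_id), .data$trial_index)
  manifest$seed <- purrr::map2_int(
    match(manifest$subject_id, subjects$subject_id), manifest$trial_index,
    function(i, k) res$trial_seeds[i, k]
  )

  trials <- purrr::pmap(
    list(manifest$subject_id, manifest$trial_index, manifest$seed),
    function(sid, k, sd_k) {
      i <- match(sid, subjects$subject_id)
      simulate_trial(res$profiles[[i]], trial_index = k, seed = sd_k,
                     subject_id = sid)
    }
  )
  names(trials) <- paste0(manifest$subject_id, "_trial", manifest$trial_index)

  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    manifest$path <- file.path(write_dir, paste0(names(trials), ".tsv"))
    purrr::walk2(trials, manifest$path,
                 function(tr, p) write_imu_recording(tr$recording, p))
    write_manifest(dplyr::left_join(manifest, res$scores,
                                    by = c("subject_id", "group")),
                   file.path(write_dir, "manifest.yaml"))
  }

  structure(list(manifest = manifest, trials = trials, scores = res$scores,
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d PD + %d control subjects x %d trials = %d recordings (seed %d)\n",
              x$spec$n_pd, x$spec$n_control, x$spec$n_trials,
              length(x$trials), x$spec$seed))
  invisible(x)
}
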