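test_that("simulation is deterministic under its seed", {
  a <- simulate_trial(subject_profile("PD"), 2, seed = 17)
  b <- simulate_trial(subject_profile("PD"), 2, seed = 17)
  expect_identical(a, b)
  c_ <- simulate_trial(subject_profile("PD"), 2, seed = 18)
  expect_false(identical(a$recording$acc_ap, c_$recording$acc_ap))

  co1 <- simulate_cohort(cohort_spec(n_pd = 3, n_control = 2, seed = 5))
  co2 <- simulate_cohort(cohort_spec(n_pd = 3, n_control = 2, seed = 5))
  expect_identical(co1$manifest, co2$manifest)
  expect_identical(co1$trials, co2$trials)
  expect_identical(co1$scores, co2$scores)
})

test_that("default cohort matches the study design counts", {
  spec <- cohort_spec()
  expect_identical(spec$n_pd, 31L)
  expect_identical(spec$n_control, 6L)
  expect_identical(spec$n_trials, 3L)
  co <- simulate_cohort(cohort_spec(n_pd = 4, n_control = 2, seed = 9))
  expect_equal(length(co$trials), 18)            # (4 + 2) subjects x 3 trials
  expect_equal(nrow(co$scores), 6)
  expect_equal(nrow(co$manifest), 18)
})

test_that("control walking spectra peak at the stride and step harmonics", {
  pr <- subject_profile("control", spectral_broadening = 0, noise_sd = 0,
                        gyro_noise_sd = 0)
  tr <- simulate_trial(pr, seed = 21)
  walk1 <- tr$truth[tr$truth$phase == "walk1", ]
  seg <- tr$recording$acc_ap[walk1$start:(walk1$end - 1)]
  p <- normalized_psd(seg, 100)
  peaks <- p$freq[p$norm_psd > 0.5]
  expect_true(all(abs(peaks - 2) < 0.3 | abs(peaks - 4) < 0.3))
  expect_gt(max(p$norm_psd[abs(p$freq - 2) < 0.3]), 0.5)
})

test_that("freeze episodes raise FR and zero intensity is a null perturbation", {
  ep <- tibble::tibble(phase = "turn", start_offset_s = 0.4,
                       duration_s = 1.2, intensity_g = 0.18)
  with_ep <- subject_profile("PD", freeze_episodes = ep)
  without <- subject_profile("PD")
  for (seed in c(7, 23)) {
    t1 <- simulate_trial(with_ep, seed = seed)
    t0 <- simulate_trial(without, seed = seed)
    fr_turn <- function(tr) {
      ph <- tr$truth[tr$truth$phase == "turn", ]
      frequency_ratio(tr$recording$acc_ap[ph$start:(ph$end - 1)], 100)
    }
    expect_gt(fr_turn(t1), fr_turn(t0))
  }
  zero <- ep
  zero$intensity_g <- 0
  tz <- simulate_trial(subject_profile("PD", freeze_episodes = zero), seed = 7)
  t0 <- simulate_trial(without, seed = 7)
  expect_identical(tz$recording, t0$recording)
})

test_that("profile validation enforces the freeze-placement contract", {
  ep <- tibble::tibble(phase = "turn", start_offset_s = 2.5, duration_s = 1,
                       intensity_g = 0.1)
  expect_error(subject_profile("PD", freeze_episodes = ep),
               "past the end", class = "sparctug_spec_error")
  expect_error(
    subject_profile("control", freeze_episodes = tibble::tibble(
      phase = "turn", start_offset_s = 0.1, duration_s = 0.5, intensity_g = 0.1)),
    "control", class = "sparctug_spec_error"
  )
  expect_error(subject_profile("PD", phase_durations = c(1, 2, -1, 2, 2)),
               class = "sparctug_spec_error")
})

test_that("clinical scores sit in range and track degradation", {
  co <- simulate_cohort(cohort_spec(n_pd = 12, n_control = 4, seed = 31))
  sc <- co$scores
  expect_true(all(sc$fogq >= 0 & sc$fogq <= 24))
  expect_true(all(sc$hy >= 1 & sc$hy <= 5))
  expect_true(all(sc$mmse >= 0 & sc$mmse <= 30))
  expect_true(all(sc$postural_stability >= 0 & sc$postural_stability <= 4))
  pd <- sc[sc$group == "PD", ]
  expect_gt(cor(pd$degradation, pd$fogq), 0.3)
  expect_lt(mean(sc$fogq[sc$group == "control"]), mean(pd$fogq))
})

test_that("FOG-Q correlates negatively with SPARC in the pre-sit phase", {
  cohort <- analysed_default_cohort()
  scores <- cohort$cohort$scores
  pd_ids <- scores$subject_id[scores$group == "PD"]
  for (ch in c("acc_l_ml", "acc_a_v")) {
    by_subj <- cohort$smoothness |>
      dplyr::filter(channel == ch, phase == "turn_stand_to_sit") |>
      dplyr::group_by(subject_id) |>
      dplyr::summarise(sparc = mean(sparc), .groups = "drop") |>
      dplyr::left_join(scores, by = "subject_id")
    expect_lt(pearson_cor(by_subj$fogq, by_subj$sparc)$r, 0)
  }
  # turning is the most affected movement: within the PD group alone the
  # link survives on the turn phase
  pd <- cohort$smoothness |>
    dplyr::filter(channel == "acc_l_total", phase == "turn",
                  subject_id %in% pd_ids) |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(sparc = mean(sparc), .groups = "drop") |>
    dplyr::left_join(scores, by = "subject_id")
  expect_lt(pearson_cor(pd$fogq, pd$sparc)$r, 0)
})

test_that("cohorts can be written to disk and read back via the manifest", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(cohort_spec(n_pd = 2, n_control = 1, seed = 13),
                        write_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  man <- read_manifest(file.path(dir, "manifest.yaml"))
  expect_equal(nrow(man), 9)
  rec <- read_imu_recording(man$path[[1]])
  orig <- co$trials[[1]]$recording
  expect_equal(rec$acc_ap, orig$acc_ap, tolerance = 1e-6)
  expect_identical(attr(rec, "subject_id"), attr(orig, "subject_id"))
})
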