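#' TUG segmentation configuration
#'
#' Thresholds of the yaw/pitch phase detectors. Turns are found where the
#' smoothed yaw rate exceeds `turn_rate_threshold` and the net yaw angle over
#' the interval reaches `turn_net_angle_min`; interval edges are then
#' extended outwards to where the rate falls below `edge_rate`, so the
#' reported interval covers the whole rotation, not just its fast core.
#' Postural transitions are pitch-angle excursions whose peak reaches
#' `pitch_peak_prominence`, delimited where the excursion falls below
#' `pitch_edge_frac` of its peak (floored at 1 degree).
#'
#' @param turn_rate_threshold yaw-rate core threshold in °/s (default 30).
#' @param turn_net_angle_min minimum net turn angle in degrees (default 120;
#'   the cone turn and the pre-sit turn are both close to 180°).
#' @param pitch_peak_prominence minimum pitch excursion in degrees for a
#'   sit-to-stand / stand-to-sit event (default 15).
#' @param smoothing_window_s moving-average smoothing applied to rates and
#'   angles before thresholding, in seconds (default 0.25).
#' @param edge_rate yaw rate in °/s at which a turn is considered to begin
#'   and end (default 5).
#' @param pitch_edge_frac fraction of the peak pitch excursion delimiting a
#'   transition interval (default 0.05).
#' @param min_gap_s runs above threshold closer than this are merged into one
#'   event (default 0.5 s).
#' @return a list of class `segmentation_config`.
#' @export
segmentation_config <- function(turn_rate_threshold = 30, turn_net_angle_min = 120,
                                pitch_peak_prominence = 15,
                                smoothing_window_s = 0.25, edge_rate = 5,
                                pitch_edge_frac = 0.05, min_gap_s = 0.5) {
  vals <- c(turn_rate_threshold, turn_net_angle_min, pitch_peak_prominence,
            smoothing_window_s, edge_rate, pitch_edge_frac, min_gap_s)
  if (any(vals <= 0)) stop_fmt("value_error", "all segmentation thresholds must be positive")
  structure(list(turn_rate_threshold = turn_rate_threshold,
                 turn_net_angle_min = turn_net_angle_min,
                 pitch_peak_prominence = pitch_peak_prominence,
                 smoothing_window_s = smoothing_window_s,
                 edge_rate = edge_rate, pitch_edge_frac = pitch_edge_frac,
                 min_gap_s = min_gap_s),
            class = "segmentation_config")
}

#' Integrate an angular rate to an angle
#'
#' Cumulative trapezoidal integration of a gyroscope rate channel, starting
#' at 0 degrees. A constant sensor bias can optionally be estimated from an
#' initial quiet window and subtracted before integration (`bias_window`
#' frames); `detrend = TRUE` instead removes a least-squares line from the
#' integrated angle. Bias-window correction is the default route for
#' segmentation: detrending is appropriate for angles that return to
#' baseline (pitch) but biases the net angle of a monotone turn sequence
#' (yaw), where the integrated angle is a staircase.
#'
#' @param rate angular rate in °/s.
#' @param sample_rate sampling rate in Hz.
#' @param bias_window frames used to estimate a constant rate bias (0 = none).
#' @param detrend remove a linear trend from the integrated angle.
#' @return angle series in degrees, same length as `rate`.
#' @export
integrate_rate <- function(rate, sample_rate, bias_window = 0L, detrend = FALSE) {
  if (length(rate) == 0) stop_fmt("length_error", "empty rate series")
  if (bias_window > 0 && length(rate) > bias_window) {
    rate <- rate - mean(rate[seq_len(bias_window)])
  }
  ang <- cumtrapz_(rate, 1 / sample_rate)
  if (detrend) ang <- remove_drift(ang, preprocess_config())
  ang
}

# runs of |x| > threshold, merged across gaps shorter than min_gap samples,
# edges extended outwards while |x| > edge
threshold_events <- function(x, threshold, edge, min_gap) {
  runs <- true_runs(abs(x) > threshold)
  if (nrow(runs) == 0) return(runs)
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs[i, "start"] - merged[nrow(merged), "end"] <= min_gap) {
        merged[nrow(merged), "end"] <- runs[i, "end"]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
  }
  n <- length(x)
  for (i in seq_len(nrow(merged))) {
    s <- merged[i, "start"]
    while (s > 1 && abs(x[s - 1]) > edge) s <- s - 1L
    e <- merged[i, "end"]
    while (e < n && abs(x[e + 1]) > edge) e <- e + 1L
    merged[i, "start"] <- s
    merged[i, "end"] <- e
  }
  merged
}

#' Detect the two TUG turns from the yaw angle
#'
#' The TUG contains exactly two turns: the mid-test turn around the cone and
#' the pre-sit turn, both close to 180 degrees. Candidate intervals are runs
#' where the smoothed yaw rate magnitude exceeds the core threshold; each is
#' extended to the `edge_rate` crossings and kept if its net yaw angle
#' reaches `turn_net_angle_min`.
#'
#' @param yaw_angle integrated yaw angle in degrees (see [integrate_rate]).
#' @param sample_rate sampling rate in Hz.
#' @param cfg a [segmentation_config].
#' @return tibble with columns `turn`, `start`, `end` (1-based, half-open
#'   `[start, end)`), and `net_angle_deg`, ordered in time; exactly two rows.
#' @export
detect_turns <- function(yaw_angle, sample_rate, cfg = segmentation_config()) {
  n <- length(yaw_angle)
  if (n < 3) stop_fmt("length_error", "yaw angle series too short")
  w <- max(1L, round(cfg$smoothing_window_s * sample_rate))
  rate <- moving_average(c(diff(yaw_angle), 0) * sample_rate, w)
  ev <- threshold_events(rate, cfg$turn_rate_threshold, cfg$edge_rate,
                         round(cfg$min_gap_s * sample_rate))
  if (nrow(ev) > 0) {
    net <- abs(yaw_angle[ev[, "end"]] - yaw_angle[ev[, "start"]])
    ev <- ev[net >= cfg$turn_net_angle_min, , drop = FALSE]
    net <- net[net >= cfg$turn_net_angle_min]
  } else {
    net <- numeric(0)
  }
  if (nrow(ev) < 2) {
    stop_fmt("segmentation_error",
             "expected 2 turns >= ", cfg$turn_net_angle_min, " deg, found ",
             nrow(ev),
             if (nrow(ev) > 0) paste0(" (net angle ",
                                      paste(round(net, 1), collapse = ", "),
                                      " deg)") else "")
  }
  if (nrow(ev) > 2) {
    keep <- sort(order(net, decreasing = TRUE)[1:2])
    ev <- ev[keep, , drop = FALSE]
    net <- net[keep]
  }
  tibble(turn = 1:2, start = as.integer(ev[, "start"]),
         end = as.integer(ev[, "end"]) + 1L, net_angle_deg = net)
}

#' Detect sit-to-stand and stand-to-sit from the pitch angle
#'
#' Rising from the chair and sitting back down show up as the first and last
#' large pitch excursions (forward trunk lean and return). An excursion
#' qualifies when its peak deviation from the starting angle reaches
#' `pitch_peak_prominence` degrees; its interval extends to where the
#' deviation falls below `pitch_edge_frac` of the peak (at least 1 degree).
#'
#' @param pitch_angle integrated pitch angle in degrees.
#' @param sample_rate sampling rate in Hz.
#' @param cfg a [segmentation_config].
#' @return tibble with columns `transition` (`"sit_to_stand"`,
#'   `"stand_to_sit"`), `start`, `end` (half-open), `peak_deg`.
#' @export
detect_postural_transitions <- function(pitch_angle, sample_rate,
                                        cfg = segmentation_config()) {
  n <- length(pitch_angle)
  if (n < 3) stop_fmt("length_error", "pitch angle series too short")
  w <- max(1L, round(cfg$smoothing_window_s * sample_rate))
  dev <- moving_average(pitch_angle - pitch_angle[[1]], w)
  core <- threshold_events(dev, cfg$pitch_peak_prominence / 2,
                           max(1, cfg$pitch_edge_frac * cfg$pitch_peak_prominence),
                           round(cfg$min_gap_s * sample_rate))
  peaks <- numeric(0)
  keep <- logical(nrow(core))
  for (i in seq_len(nrow(core))) {
    pk <- max(abs(dev[core[i, "start"]:core[i, "end"]]))
    keep[i] <- pk >= cfg$pitch_peak_prominence
    peaks <- c(peaks, pk)
  }
  core <- core[keep, , drop = FALSE]
  peaks <- peaks[keep]
  if (nrow(core) < 2) {
    stop_fmt("segmentation_error",
             "expected sit-to-stand and stand-to-sit pitch excursions >= ",
             cfg$pitch_peak_prominence, " deg, found ", nrow(core))
  }
  # refine each edge to the excursion's own 5%-of-peak crossing
  refine <- function(i) {
    s <- core[i, "start"]; e <- core[i, "end"]
    thr <- max(1, cfg$pitch_edge_frac * peaks[i])
    while (s > 1 && abs(dev[s - 1]) > thr) s <- s - 1L
    while (e < n && abs(dev[e + 1]) > thr) e <- e + 1L
    c(s, e)
  }
  first <- refine(1L)
  last <- refine(nrow(core))
  tibble(transition = c("sit_to_stand", "stand_to_sit"),
         start = as.integer(c(first[1], last[1])),
         end = as.integer(c(first[2], last[2])) + 1L,
         peak_deg = c(peaks[1], peaks[length(peaks)]))
}

tug_phases <- function() {
  c("sit_to_stand", "walk1", "turn", "walk2", "turn_stand_to_sit")
}

new_tug_segmentation <- function(phases, sample_rate, onset, turn2_end = NA_integer_) {
  out <- new_tibble(phases, class = "tug_segmentation")
  attr(out, "sample_rate") <- sample_rate
  attr(out, "onset") <- onset
  attr(out, "turn2_end") <- turn2_end
  out
}

#' Segment a TUG recording into its five phases
#'
#' Composes the movement-onset gate, the pitch-excursion detector and the
#' yaw-turn detector into the ordered, contiguous TUG phases: sit-to-stand,
#' walk 1, turn (around the cone), walk 2, and the combined turn-and-stand-
#' to-sit phase that ends the test when the subject is seated. The fifth
#' phase merges the pre-sit turn with sitting down, matching how it is
#' analysed and reported; the internal end of that second turn is kept as an
#' attribute (`turn2_end`) for diagnostics. Intervals are 1-based half-open
#' `[start, end)` sample ranges; consecutive phases share their boundary, so
#' the phase durations sum to the full-test duration exactly.
#'
#' Onset is detected on the resultant linear acceleration and that single
#' index gates all channels. Walking phases include the gait initiation and
#' termination transients adjacent to them.
#'
#' @param rec an [imu_recording].
#' @param pcfg a [preprocess_config].
#' @param scfg a [segmentation_config].
#' @return a `tug_segmentation`: tibble with columns `phase`, `start`, `end`,
#'   `duration_s` (five rows in test order), with the sampling rate, onset
#'   index and second-turn split as attributes. `tug_durations()` summarises
#'   it to one row including the total TUG time.
#' @export
segment_tug <- function(rec, pcfg = preprocess_config(),
                        scfg = segmentation_config()) {
  fs <- attr(rec, "sample_rate")
  res <- resultant_total(rec$acc_v, rec$acc_ml, rec$acc_ap)
  onset <- detect_onset(res, pcfg)

  yaw <- integrate_rate(rec$gyro_yaw, fs, bias_window = pcfg$noise_window)
  # the test starts and ends seated upright, so the pitch angle is anchored
  # to its baseline at both ends; this removes residual gyro-bias drift that
  # a leading noise window alone cannot (yaw keeps a net rotation, so it
  # only gets the bias-window correction)
  pitch <- anchor_detrend(
    integrate_rate(rec$gyro_pitch, fs, bias_window = pcfg$noise_window),
    w = pcfg$noise_window %/% 2
  )

  turns <- tryCatch(detect_turns(yaw, fs, scfg), error = function(e) {
    stop_fmt("segmentation_error", "turn detection failed: ", conditionMessage(e))
  })
  trans <- tryCatch(detect_postural_transitions(pitch, fs, scfg), error = function(e) {
    stop_fmt("segmentation_error", "postural-transition detection failed: ",
             conditionMessage(e))
  })

  sts_end <- trans$end[[1]]
  sit_end <- trans$end[[2]]
  t1s <- turns$start[[1]]; t1e <- turns$end[[1]]
  t2s <- turns$start[[2]]; t2e <- turns$end[[2]]
  full_start <- min(onset, trans$start[[1]])
  if (!(full_start < sts_end && sts_end <= t1s && t1e <= t2s && t2e <= sit_end)) {
    stop_fmt("segmentation_error",
             "detected events out of TUG order (onset ", onset,
             ", sit-to-stand end ", sts_end, ", turn1 [", t1s, ",", t1e,
             "), turn2 [", t2s, ",", t2e, "), stand-to-sit end ", sit_end, ")")
  }
  starts <- c(full_start, sts_end, t1s, t1e, t2s)
  ends <- c(sts_end, t1s, t1e, t2s, sit_end)
  phases <- tibble(
    phase = tug_phases(),
    start = as.integer(starts),
    end = as.integer(ends),
    duration_s = (ends - starts) / fs
  )
  new_tug_segmentation(phases, fs, onset, turn2_end = t2e)
}

#' @rdname segment_tug
#' @param seg a `tug_segmentation`.
#' @export
tug_durations <- function(seg) {
  wide <- stats::setNames(as.list(seg$duration_s), seg$phase)
  dplyr::bind_cols(as_tibble(wide), tibble(total_s = sum(seg$duration_s)))
}

#' @export
print.tug_segmentation <- function(x, ...) {
  cat(sprintf("<tug_segmentation> %d phases, total %.2f s @ %g Hz\n",
              nrow(x), sum(x$duration_s), attr(x, "sample_rate")))
  NextMethod()
}

#' Export a segmentation as a BED-like TSV
#'
#' One row per phase: recording id, phase label, start sample, end sample
#' (half-open) and duration in seconds.
#'
#' @param seg a `tug_segmentation`.
#' @param path output file.
#' @param recording_id identifier written in the first column.
#' @export
write_segmentation <- function(seg, path, recording_id = "recording") {
  out <- dplyr::mutate(as_tibble(seg), recording_id = recording_id,
                       .before = 1)
  readr::write_tsv(out, path)
  invisible(path)
}
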