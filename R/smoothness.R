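#' Spectral and SPARC configuration
#'
#' Controls the power-spectral-density estimate behind the SPARC smoothness
#' metric. Only frequencies up to `f_high` (10 Hz by default) take part in
#' the arc length: the movements of the TUG live below 10 Hz and higher
#' frequencies are noise. Short phase segments are tiled end-to-end — by a
#' factor of 4 for the five individual phases, 2 for the full test — before
#' zero padding, which sharpens the dominant peaks and increases the
#' sensitivity of the metric on segments only a few strides long.
#'
#' @param f_low lower integration bound in Hz (default 0).
#' @param f_high upper integration bound in Hz (default 10).
#' @param tile_factor_phase tiling factor for individual phases (default 4).
#' @param tile_factor_full tiling factor for the full test (default 2).
#' @param zero_pad FFT length: `"pow2x4"` (default) pads to four times the
#'   next power of two above the tiled length; an integer fixes the length.
#' @param psd_estimator only `"periodogram"` (rectangular window) is
#'   implemented.
#' @return a list of class `smoothness_config`.
#' @export
smoothness_config <- function(f_low = 0, f_high = 10, tile_factor_phase = 4L,
                              tile_factor_full = 2L, zero_pad = "pow2x4",
                              psd_estimator = "periodogram") {
  if (f_low < 0 || f_high <= f_low) stop_fmt("value_error", "need 0 <= f_low < f_high")
  if (tile_factor_phase < 1 || tile_factor_full < 1) {
    stop_fmt("value_error", "tile factors must be >= 1")
  }
  psd_estimator <- match.arg(psd_estimator, "periodogram")
  structure(list(f_low = f_low, f_high = f_high,
                 tile_factor_phase = as.integer(tile_factor_phase),
                 tile_factor_full = as.integer(tile_factor_full),
                 zero_pad = zero_pad, psd_estimator = psd_estimator),
            class = "smoothness_config")
}

#' Freeze and locomotor frequency bands
#'
#' Band definitions of the frequency-ratio freeze index: trembling-like
#' freezing concentrates power in 3–8 Hz (freeze band) while normal stepping
#' lives in 0.5–3 Hz (locomotor band). The shared 3 Hz edge belongs to the
#' locomotor band: the bands are `[0.5, 3]` and `(3, 8]`.
#'
#' @param freeze numeric length-2 vector, freeze band in Hz.
#' @param locomotor numeric length-2 vector, locomotor band in Hz.
#' @return a list of class `freeze_bands`.
#' @export
freeze_bands <- function(freeze = c(3, 8), locomotor = c(0.5, 3)) {
  structure(list(freeze = freeze, locomotor = locomotor), class = "freeze_bands")
}

#' Tile a segment end-to-end
#'
#' Repeats a (mean-subtracted) segment `factor` times. The mean is removed
#' first so that the junctions between copies introduce no step
#' discontinuity from a DC offset.
#'
#' @param series numeric samples.
#' @param factor integer repetition factor, at least 1.
#' @return numeric vector of length `factor * length(series)`.
#' @export
tile_segment <- function(series, factor) {
  if (length(factor) != 1 || is.na(factor) || factor < 1) {
    stop_fmt("value_error", "tile factor must be an integer >= 1")
  }
  rep(remove_dc(series), as.integer(factor))
}

#' Normalized power spectral density
#'
#' Rectangular-window periodogram of the mean-subtracted series, zero padded
#' for a fine frequency grid, restricted to `(f_low, f_high]` and divided by
#' its maximum there, so the profile lies in `[0, 1]` with a maximum of
#' exactly 1. The DC bin is dropped before normalization (the mean, i.e.
#' gravity on accelerometer channels, has already been subtracted).
#'
#' @param series numeric samples, at least 8.
#' @param sample_rate sampling rate in Hz.
#' @param cfg a [smoothness_config].
#' @return a `spectral_profile`: tibble with columns `freq` (Hz, strictly
#'   increasing within the band) and `norm_psd`, plus `f_low`, `f_high`,
#'   `resolution` and `sample_rate` attributes.
#' @export
normalized_psd <- function(series, sample_rate, cfg = smoothness_config()) {
  n <- length(series)
  if (n < 8) stop_fmt("length_error", "need at least 8 samples for a spectrum")
  x <- remove_dc(series)
  if (all(x == 0)) stop_fmt("degenerate_spectrum", "all-zero series has no defined spectrum")
  npad <- if (is.numeric(cfg$zero_pad)) max(as.integer(cfg$zero_pad), n)
          else 4L * 2L^ceiling(log2(n))
  psd <- Mod(fft(c(x, numeric(npad - n))))^2 / (n * sample_rate)
  nhalf <- floor(npad / 2)
  freq <- (0:nhalf) * sample_rate / npad
  psd <- psd[1:(nhalf + 1)]
  keep <- freq > cfg$f_low & freq <= cfg$f_high
  freq <- freq[keep]
  psd <- psd[keep]
  if (length(freq) < 2 || max(psd) == 0) {
    stop_fmt("degenerate_spectrum", "no spectral content in the analysis band")
  }
  out <- new_tibble(tibble(freq = freq, norm_psd = psd / max(psd)),
                    class = "spectral_profile")
  attr(out, "f_low") <- cfg$f_low
  attr(out, "f_high") <- cfg$f_high
  attr(out, "resolution") <- sample_rate / npad
  attr(out, "sample_rate") <- sample_rate
  out
}

#' Spectral arc length (SPARC)
#'
#' The negative arc length of the normalized power spectrum over the
#' integration band, with the frequency axis scaled to unit length:
#' \deqn{SPARC = -\sum_i \sqrt{\left(\frac{\Delta w_i}{f_{high}-f_{low}}\right)^2
#'   + \left(\Delta normPSD_i\right)^2}.}
#' A flat band-limited spectrum gives exactly −1 (the scaled frequency axis
#' alone); every additional spectral feature lengthens the curve, so SPARC
#' is always at most −1 and lower values mean less smooth movement. The
#' profile is extended to the full `[f_low, f_high]` band by constant
#' extrapolation before summing, so the bound holds regardless of where the
#' discrete grid starts and ends.
#'
#' @param profile a `spectral_profile` from [normalized_psd], or any data
#'   frame with `freq` and `norm_psd` columns.
#' @param f_low,f_high integration band in Hz; defaults come from the
#'   profile's attributes (0 and 10 Hz for profiles built by this package).
#' @return a single SPARC value, unitless, at most −1.
#' @export
sparc <- function(profile, f_low = NULL, f_high = NULL) {
  f_low <- f_low %||% attr(profile, "f_low") %||% 0
  f_high <- f_high %||% attr(profile, "f_high") %||% 10
  freq <- profile$freq
  p <- profile$norm_psd
  if (is.null(freq) || is.null(p) || length(freq) < 2) {
    stop_fmt("value_error", "profile needs freq and norm_psd with at least 2 bins")
  }
  if (freq[[1]] > f_low) {
    freq <- c(f_low, freq)
    p <- c(p[[1]], p)
  }
  nb <- length(freq)
  if (freq[[nb]] < f_high) {
    freq <- c(freq, f_high)
    p <- c(p, p[[nb]])
  }
  -sum(sqrt((diff(freq) / (f_high - f_low))^2 + diff(p)^2))
}

#' SPARC of a raw segment
#'
#' Conditions one phase segment and returns its SPARC: tile (factor 4 for an
#' individual phase, 2 for the full test), estimate the normalized PSD, take
#' the negative arc length. Because the spectrum is normalized, the result
#' is exactly invariant to amplitude scaling of the segment.
#'
#' @param series samples of one phase (one channel).
#' @param sample_rate sampling rate in Hz.
#' @param phase_kind `"phase"` for one of the five TUG phases, `"full"` for
#'   the whole test (selects the tiling factor).
#' @param cfg a [smoothness_config].
#' @return a SPARC value.
#' @export
sparc_of_segment <- function(series, sample_rate, phase_kind = c("phase", "full"),
                             cfg = smoothness_config()) {
  phase_kind <- match.arg(phase_kind)
  factor <- if (phase_kind == "full") cfg$tile_factor_full else cfg$tile_factor_phase
  sparc(normalized_psd(tile_segment(series, factor), sample_rate, cfg))
}

#' Frequency-ratio freeze index
#'
#' FR is the squared band power in the 3–8 Hz freeze band divided by the
#' squared band power in the 0.5–3 Hz locomotor band, computed on the
#' anteroposterior acceleration of the full test. Values near 0 indicate
#' healthy gait, around 0.3 parkinsonian gait without freezing, and around 2
#' gait with freezing episodes. Being a power ratio it is invariant to
#' amplitude scaling of the signal.
#'
#' The generic accepts either a raw series (with `sample_rate`) or an
#' already-computed `spectral_profile`; band powers are trapezoidal
#' integrals of the PSD over each band, the 3 Hz edge belonging to the
#' locomotor band.
#'
#' @param x numeric series (at least 2 s of data) or a `spectral_profile`.
#' @param sample_rate sampling rate in Hz (series method).
#' @param bands a [freeze_bands].
#' @param pad_factor zero-padding factor of the periodogram (series method).
#' @param ... passed between methods.
#' @return a single non-negative FR value.
#' @export
frequency_ratio <- function(x, ...) UseMethod("frequency_ratio")

#' @rdname frequency_ratio
#' @export
frequency_ratio.numeric <- function(x, sample_rate, bands = freeze_bands(),
                                    pad_factor = 4, ...) {
  n <- length(x)
  if (n < 2 * sample_rate) {
    stop_fmt("length_error", "need at least 2 s of signal to resolve the bands")
  }
  x <- remove_dc(x)
  npad <- pad_factor * 2L^ceiling(log2(n))
  psd <- Mod(fft(c(x, numeric(npad - n))))^2 / (n * sample_rate)
  nhalf <- floor(npad / 2)
  freq <- (0:nhalf) * sample_rate / npad
  fr_from_psd(freq, psd[1:(nhalf + 1)], bands)
}

#' @rdname frequency_ratio
#' @export
frequency_ratio.spectral_profile <- function(x, bands = freeze_bands(), ...) {
  fr_from_psd(x$freq, x$norm_psd, bands)
}

#' @rdname frequency_ratio
#' @export
frequency_ratio.data.frame <- function(x, bands = freeze_bands(), ...) {
  fr_from_psd(x$freq, x$norm_psd, bands)
}

fr_from_psd <- function(freq, psd, bands = freeze_bands()) {
  band_power <- function(lo, hi, open_left = FALSE) {
    keep <- if (open_left) freq > lo & freq <= hi else freq >= lo & freq <= hi
    trapz_(freq[keep], psd[keep])
  }
  p_loc <- band_power(bands$locomotor[[1]], bands$locomotor[[2]])
  p_frz <- band_power(bands$freeze[[1]], bands$freeze[[2]], open_left = TRUE)
  if (p_loc <= 0) {
    stop_fmt("degenerate_spectrum",
             "zero power in the locomotor band (", bands$locomotor[[1]], "-",
             bands$locomotor[[2]], " Hz): frequency ratio undefined")
  }
  p_frz^2 / p_loc^2
}

smoothness_channels <- function() {
  c("acc_l_v", "acc_l_ml", "acc_l_ap", "acc_l_total",
    "acc_a_v", "acc_a_ml", "acc_a_ap", "acc_a_total")
}

#' Per-phase smoothness of one recording
#'
#' Computes SPARC for all 8 channels — linear acceleration (Acc L) and
#' derived angular acceleration (Acc A), each on the V / ML / AP axes plus
#' the resultant "total" — over the five TUG phases and the full test
#' (48 values), and the frequency-ratio freeze index on the anteroposterior
#' linear acceleration over the full test. Angular-acceleration axes follow
#' the rotation axes: yaw rate differentiates to Acc A V, pitch to Acc A ML,
#' roll to Acc A AP. Each axis channel is DC- and drift-corrected over the
#' full test interval before slicing; the total channels are mean-subtracted
#' resultants.
#'
#' @param rec an [imu_recording].
#' @param seg its `tug_segmentation` (see [segment_tug]).
#' @param cfg a [smoothness_config].
#' @param pcfg a [preprocess_config].
#' @return a `smoothness_result`: tibble with columns `subject_id`, `group`,
#'   `trial_index`, `channel`, `phase`, `sparc` and `fr` (FR only on the
#'   full-test anteroposterior linear-acceleration row, `NA` elsewhere).
#' @export
analyze_recording <- function(rec, seg, cfg = smoothness_config(),
                              pcfg = preprocess_config()) {
  fs <- attr(rec, "sample_rate")
  full_start <- seg$start[[1]]
  full_end <- seg$end[[nrow(seg)]]
  idx <- full_start:(full_end - 1L)

  cond <- function(x) remove_drift(remove_dc(x[idx]), pcfg)
  acc <- list(v = cond(rec$acc_v), ml = cond(rec$acc_ml), ap = cond(rec$acc_ap))
  ang_rate <- list(v = rec$gyro_yaw, ml = rec$gyro_pitch, ap = rec$gyro_roll)
  ang <- lapply(ang_rate, function(r) cond(angular_acceleration(r, fs)))

  chans <- list(
    acc_l_v = acc$v, acc_l_ml = acc$ml, acc_l_ap = acc$ap,
    acc_l_total = resultant_total(rec$acc_v[idx], rec$acc_ml[idx], rec$acc_ap[idx]),
    acc_a_v = ang$v, acc_a_ml = ang$ml, acc_a_ap = ang$ap,
    acc_a_total = resultant_total(ang$v, ang$ml, ang$ap)
  )

  bounds <- rbind(cbind(seg$start, seg$end), c(full_start, full_end)) - full_start + 1L
  phase_names <- c(seg$phase, "full")
  kinds <- c(rep("phase", nrow(seg)), "full")

  rows <- purrr::imap(chans, function(series, ch) {
    vals <- purrr::map_dbl(seq_along(phase_names), function(i) {
      slice <- series[bounds[i, 1]:(bounds[i, 2] - 1L)]
      tryCatch(
        sparc_of_segment(slice, fs, kinds[[i]], cfg),
        error = function(e) stop_fmt(
          "analysis_error", "SPARC failed for channel ", ch, ", phase ",
          phase_names[[i]], ": ", conditionMessage(e))
      )
    })
    tibble(channel = ch, phase = phase_names, sparc = vals)
  })
  out <- dplyr::bind_rows(rows)
  out$fr <- NA_real_
  fr_val <- frequency_ratio(chans$acc_l_ap, sample_rate = fs)
  out$fr[out$channel == "acc_l_ap" & out$phase == "full"] <- fr_val
  out <- dplyr::mutate(out,
                       subject_id = attr(rec, "subject_id"),
                       group = attr(rec, "group"),
                       trial_index = attr(rec, "trial_index"),
                       .before = 1)
  new_tibble(out, class = "smoothness_result")
}

#' Average smoothness across the three trials
#'
#' Per-channel, per-phase arithmetic mean of the SPARC values (and FR) of
#' one subject's trials; the averaged table carries `trial_index = NA` and
#' the number of trials averaged in `n_trials`.
#'
#' @param results a list of `smoothness_result` tables for one subject, or a
#'   single table holding that subject's trials.
#' @return a `smoothness_result` tibble with one row per channel and phase.
#' @export
average_trials <- function(results) {
  tbl <- if (is.data.frame(results)) results else dplyr::bind_rows(results)
  subj <- unique(tbl$subject_id)
  if (length(subj) != 1) {
    stop_fmt("metadata_error", "trials from different subjects: ",
             paste(subj, collapse = ", "))
  }
  out <- tbl |>
    dplyr::group_by(.data$subject_id, .data$group, .data$channel, .data$phase) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      sparc = mean(.data$sparc),
      fr = if (all(is.na(.data$fr))) NA_real_ else mean(.data$fr, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(trial_index = NA_integer_, .after = "group")
  new_tibble(out, class = "smoothness_result")
}

#' Write a smoothness table as tidy CSV
#'
#' @param result a `smoothness_result`.
#' @param path output file.
#' @export
write_smoothness <- function(result, path) {
  readr::write_csv(as_tibble(result), path)
  invisible(path)
}
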