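#' Signal-conditioning configuration
#'
#' Parameters of the movement-onset gate and the DC/drift removal applied to
#' every channel before spectral analysis. The onset rule declares movement
#' when the mean of a 10-frame moving window deviates from the initial
#' baseline by more than three times the standard deviation of the first
#' 100 frames of quiet sitting; all three constants are exposed here.
#'
#' @param noise_window frames of initial quiet signal used to estimate the
#'   noise floor (default 100, i.e. 1 s at 100 Hz).
#' @param moving_window frames of the moving detection window (default 10).
#' @param threshold_k onset threshold as a multiple of the noise SD (default 3).
#' @param sd_floor lower bound on the noise SD in signal units, guarding the
#'   degenerate constant-baseline case (default 1e-6 g).
#' @param drift_method `"linear-detrend"` (default) removes a least-squares
#'   line; `"moving-mean"` subtracts a centred moving mean.
#' @param moving_mean_window frames of the moving-mean drift window
#'   (default 100, i.e. a 1 s window at 100 Hz, passing only trends slower
#'   than about 0.25 Hz).
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(noise_window = 100L, moving_window = 10L,
                              threshold_k = 3, sd_floor = 1e-6,
                              drift_method = c("linear-detrend", "moving-mean"),
                              moving_mean_window = 100L) {
  drift_method <- match.arg(drift_method)
  noise_window <- as.integer(noise_window)
  moving_window <- as.integer(moving_window)
  if (moving_window < 1L || noise_window < moving_window) {
    stop_fmt("value_error", "need noise_window >= moving_window >= 1")
  }
  if (threshold_k <= 0 || sd_floor <= 0) {
    stop_fmt("value_error", "threshold_k and sd_floor must be positive")
  }
  structure(list(noise_window = noise_window, moving_window = moving_window,
                 threshold_k = threshold_k, sd_floor = sd_floor,
                 drift_method = drift_method,
                 moving_mean_window = as.integer(moving_mean_window)),
            class = "preprocess_config")
}

#' Movement-onset detection
#'
#' Returns the first sample index (1-based) at which the mean absolute
#' deviation of a `moving_window`-frame window from the quiet-baseline mean
#' exceeds `threshold_k` times the baseline SD. The deviation is taken from
#' the baseline *mean*, so a constant gravity offset cannot mask onset, and
#' the SD is floored at `sd_floor` so a perfectly constant baseline cannot
#' produce a spurious trigger. Samples before the returned index are
#' discarded downstream.
#'
#' The rule is invariant to adding a constant to the whole series and to
#' scaling the whole series (signal and noise alike) by a positive factor.
#'
#' @param series numeric samples (typically the resultant linear acceleration).
#' @param cfg a [preprocess_config].
#' @return integer sample index of onset.
#' @export
detect_onset <- function(series, cfg = preprocess_config()) {
  n <- length(series)
  if (n <= cfg$noise_window + cfg$moving_window) {
    stop_fmt("length_error", "series too short for onset detection (",
             n, " <= ", cfg$noise_window + cfg$moving_window, ")")
  }
  baseline <- mean(series[seq_len(cfg$noise_window)])
  noise_sd <- max(sd(series[seq_len(cfg$noise_window)]), cfg$sd_floor)
  dev <- abs(series - baseline)
  w <- cfg$moving_window
  cs <- cumsum(c(0, dev))
  starts <- seq_len(n - w + 1L)
  win_mean <- (cs[starts + w] - cs[starts]) / w
  hit <- which(win_mean > cfg$threshold_k * noise_sd)
  if (length(hit) == 0) {
    stop_fmt("no_onset", "no movement onset found: no ", w,
             "-frame window exceeded ", cfg$threshold_k, " x noise SD")
  }
  hit[[1]]
}

#' DC and drift removal
#'
#' `remove_dc()` subtracts the series mean (accelerometers pick up gravity,
#' which otherwise dominates the spectrum at DC); it is idempotent.
#' `remove_drift()` additionally removes a slow trend — a least-squares line
#' by default, or a centred moving mean — and returns a zero-mean series.
#'
#' @param series numeric samples.
#' @param cfg a [preprocess_config] (drift method and window).
#' @return numeric series of the same length.
#' @export
remove_dc <- function(series) {
  if (length(series) == 0) stop_fmt("length_error", "empty series")
  series - mean(series)
}

#' @rdname remove_dc
#' @export
remove_drift <- function(series, cfg = preprocess_config()) {
  n <- length(series)
  if (n == 0) stop_fmt("length_error", "empty series")
  if (n < 3) return(remove_dc(series))
  if (cfg$drift_method == "linear-detrend") {
    t <- seq_len(n)
    out <- stats::.lm.fit(cbind(1, t), series)$residuals
  } else {
    out <- series - moving_average(series, cfg$moving_mean_window)
  }
  remove_dc(out)
}

#' Resultant ("total") channel
#'
#' Per-sample Euclidean norm of the three axis channels, mean-subtracted so
#' that the static gravity magnitude drops out. This is the `total`
#' acceleration channel analysed alongside the per-axis channels; it is
#' invariant to permutation of the axes.
#'
#' @param x,y,z equal-length axis channels.
#' @return zero-mean resultant series.
#' @export
resultant_total <- function(x, y, z) {
  if (length(x) != length(y) || length(y) != length(z)) {
    stop_fmt("shape_error", "axis channels have different lengths (",
             length(x), ", ", length(y), ", ", length(z), ")")
  }
  remove_dc(sqrt(x^2 + y^2 + z^2))
}

#' Angular acceleration from gyroscope rate
#'
#' The gyroscope reports angular rate; angular acceleration is obtained by
#' central finite differencing (one-sided at the endpoints), preserving
#' length. For a sinusoidal rate of frequency f well below Nyquist the
#' amplitude is 2*pi*f times the rate amplitude, as for the analytic
#' derivative.
#'
#' @param gyro_rate angular rate in °/s.
#' @param sample_rate sampling rate in Hz.
#' @return angular acceleration in °/s², same length as the input.
#' @export
angular_acceleration <- function(gyro_rate, sample_rate) {
  n <- length(gyro_rate)
  if (n < 3) stop_fmt("length_error", "need at least 3 samples to differentiate")
  dt <- 1 / sample_rate
  out <- numeric(n)
  out[2:(n - 1)] <- (gyro_rate[3:n] - gyro_rate[1:(n - 2)]) / (2 * dt)
  out[1] <- (gyro_rate[2] - gyro_rate[1]) / dt
  out[n] <- (gyro_rate[n] - gyro_rate[n - 1]) / dt
  out
}
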