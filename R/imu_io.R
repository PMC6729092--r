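#' IMU recordings
#'
#' An `imu_recording` is a tibble with one row per sample and the six sensor
#' channels of a waist-worn IMU: triaxial linear acceleration in g on the
#' vertical (V), mediolateral (ML) and anteroposterior (AP) axes, and triaxial
#' angular rate in degrees per second about the yaw, pitch and roll axes.
#' Sampling is uniform; the acquisition metadata (sample rate, subject, group,
#' trial) travel as attributes so the table itself stays tidy.
#'
#' Values beyond the acquisition ranges used in the field (±8 g, ±250 °/s)
#' raise a warning, not an error: clipped samples are a data-quality signal,
#' not a structural defect.
#'
#' @param data data frame with columns `acc_v`, `acc_ml`, `acc_ap` (g) and
#'   `gyro_yaw`, `gyro_pitch`, `gyro_roll` (°/s). A `time_s` column, if
#'   present, is checked for uniform spacing and then regenerated from
#'   `sample_rate`.
#' @param sample_rate sampling frequency in Hz (default 100).
#' @param subject_id opaque subject label.
#' @param group `"PD"` or `"control"`.
#' @param trial_index trial number, 1 to 3.
#' @return A tibble of class `imu_recording` with a `time_s` column and the
#'   six channel columns.
#' @examples
#' n <- 200
#' rec <- imu_recording(
#'   data.frame(
#'     acc_v = rnorm(n, 1, 0.01), acc_ml = rnorm(n, 0, 0.01),
#'     acc_ap = sin(2 * pi * 2 * (0:(n - 1)) / 100),
#'     gyro_yaw = 0, gyro_pitch = 0, gyro_roll = 0
#'   ),
#'   subject_id = "S01", group = "control", trial_index = 1
#' )
#' rec
#' @export
imu_recording <- function(data, sample_rate = 100, subject_id = "unknown",
                          group = c("control", "PD"), trial_index = 1L) {
  group <- match.arg(group)
  chan <- imu_channels()
  missing_cols <- setdiff(chan, names(data))
  if (length(missing_cols) > 0) {
    stop_fmt("format_error", "missing channel column(s): ",
             paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop_fmt("value_error", "sample_rate must be a positive number")
  }
  n <- nrow(data)
  if (n < 1L) stop_fmt("format_error", "recording must contain at least one sample")
  lens <- vapply(data[chan], function(x) sum(!is.na(x)), integer(1))
  if (any(lens < n)) {
    stop_fmt("format_error", "channel(s) with missing values: ",
             paste(chan[lens < n], collapse = ", "))
  }
  out <- tibble(time_s = (seq_len(n) - 1) / sample_rate)
  for (ch in chan) out[[ch]] <- as.numeric(data[[ch]])
  out <- new_tibble(out, class = "imu_recording")
  attr(out, "sample_rate") <- sample_rate
  attr(out, "subject_id") <- as.character(subject_id)
  attr(out, "group") <- group
  attr(out, "trial_index") <- as.integer(trial_index)
  validate_recording(out)
}

imu_channels <- function() {
  c("acc_v", "acc_ml", "acc_ap", "gyro_yaw", "gyro_pitch", "gyro_roll")
}

#' @rdname imu_recording
#' @param rec an `imu_recording`.
#' @export
validate_recording <- function(rec) {
  acc <- as.matrix(rec[c("acc_v", "acc_ml", "acc_ap")])
  gyr <- as.matrix(rec[c("gyro_yaw", "gyro_pitch", "gyro_roll")])
  if (any(abs(acc) > 8)) {
    warn("acceleration samples beyond the +/-8 g acquisition range")
  }
  if (any(abs(gyr) > 250)) {
    warn("angular-rate samples beyond the +/-250 deg/s acquisition range")
  }
  rec
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> subject %s (%s), trial %d, %d samples @ %g Hz (%.2f s)\n",
              attr(x, "subject_id"), attr(x, "group"), attr(x, "trial_index"),
              nrow(x), attr(x, "sample_rate"),
              nrow(x) / attr(x, "sample_rate")))
  NextMethod()
}

#' Delimited-text dialect for IMU exports
#'
#' Describes the on-disk layout of a recording: delimiter, decimal mark,
#' column order and units. The canonical dialect is tab-separated with a
#' header line and columns `time_s`, `accV_g`, `accML_g`, `accAP_g`,
#' `gyroYaw_dps`, `gyroPitch_dps`, `gyroRoll_dps`. The decimal mark is fixed
#' by the dialect and never inferred from the file, so parsing is
#' locale-independent.
#'
#' @param delimiter field separator (default tab).
#' @param decimal_mark decimal separator, `"."` or `","`.
#' @param header whether a column-name line precedes the data.
#' @param time_column whether the file carries an explicit time column (first
#'   data column). When present it must be uniformly spaced.
#' @param acc_unit unit of the acceleration columns on disk: `"g"` or
#'   `"m/s2"` (converted to g on read).
#' @param gyro_unit unit of the rate columns on disk: `"dps"` or `"rad/s"`.
#' @param comment prefix of metadata lines (`# key: value`), also used to
#'   write the sidecar metadata header.
#' @return a list of class `imu_dialect`.
#' @export
imu_dialect <- function(delimiter = "\t", decimal_mark = ".", header = TRUE,
                        time_column = TRUE, acc_unit = c("g", "m/s2"),
                        gyro_unit = c("dps", "rad/s"), comment = "#") {
  structure(
    list(delimiter = delimiter, decimal_mark = decimal_mark, header = header,
         time_column = time_column, acc_unit = match.arg(acc_unit),
         gyro_unit = match.arg(gyro_unit), comment = comment),
    class = "imu_dialect"
  )
}

G_MS2 <- 9.80665

#' Convert acceleration channels to m/s^2
#'
#' Channels are stored in g, the unit the device acquires in; conversion to
#' SI is always explicit.
#'
#' @param rec an [imu_recording].
#' @return the recording with `acc_*` columns scaled by 9.80665.
#' @export
acc_to_ms2 <- function(rec) {
  for (ch in c("acc_v", "acc_ml", "acc_ap")) rec[[ch]] <- rec[[ch]] * G_MS2
  rec
}

#' Read and write IMU recordings
#'
#' `read_imu_recording()` parses one delimited-text export into a validated
#' [imu_recording]; `write_imu_recording()` is its inverse, and a
#' write-then-read round trip preserves every sample to the written numeric
#' precision. Subject metadata is looked up, in order of precedence, from the
#' explicit arguments, from `# key: value` sidecar lines at the top of the
#' file, and from a `<subject>_<group>_trial<k>` filename convention.
#'
#' @param path file to read or write.
#' @param dialect an [imu_dialect].
#' @param sample_rate fallback sampling rate in Hz when the dialect has no
#'   time column and no `sample_rate` sidecar entry.
#' @param subject_id,group,trial_index metadata overrides.
#' @return `read_imu_recording()` returns an [imu_recording];
#'   `write_imu_recording()` returns `path` invisibly.
#' @export
read_imu_recording <- function(path, dialect = imu_dialect(), sample_rate = 100,
                               subject_id = NULL, group = NULL,
                               trial_index = NULL) {
  if (!file.exists(path)) stop_fmt("io_error", "file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta_mask <- startsWith(lines, dialect$comment)
  meta <- parse_sidecar(lines[meta_mask], dialect$comment)
  body <- lines[!meta_mask & nzchar(trimws(lines))]
  if (length(body) == 0) stop_fmt("format_error", "empty file: ", path)

  expected <- c(if (dialect$time_column) "time_s",
                "accV_g", "accML_g", "accAP_g",
                "gyroYaw_dps", "gyroPitch_dps", "gyroRoll_dps")
  if (dialect$header) {
    hdr <- strsplit(body[[1]], dialect$delimiter, fixed = TRUE)[[1]]
    hdr <- trimws(hdr)
    missing_cols <- setdiff(expected, hdr)
    if (length(missing_cols) > 0) {
      stop_fmt("format_error", "missing column(s) in ", path, ": ",
               paste(missing_cols, collapse = ", "))
    }
    col_idx <- match(expected, hdr)
    body <- body[-1]
  } else {
    col_idx <- seq_along(expected)
  }
  if (length(body) == 0) stop_fmt("format_error", "no data rows in ", path)

  fields <- strsplit(body, dialect$delimiter, fixed = TRUE)
  ncol_seen <- lengths(fields)
  if (any(ncol_seen < max(col_idx))) {
    stop_fmt("format_error", "row(s) with too few fields in ", path)
  }
  mat <- matrix(unlist(lapply(fields, `[`, col_idx)), ncol = length(col_idx),
                byrow = TRUE)
  if (dialect$decimal_mark != ".") mat <- gsub(dialect$decimal_mark, ".", mat, fixed = TRUE)
  num <- suppressWarnings(matrix(as.numeric(mat), ncol = ncol(mat)))
  if (anyNA(num)) stop_fmt("format_error", "non-numeric data in ", path)
  colnames(num) <- expected

  if (dialect$time_column) {
    dt <- diff(num[, "time_s"])
    if (length(dt) > 0) {
      if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 + 1e-4 * stats::median(dt)) {
        stop_fmt("format_error", "time column is not uniformly spaced in ", path)
      }
      sample_rate <- 1 / stats::median(dt)
    }
  }
  if (!is.null(meta$sample_rate)) sample_rate <- as.numeric(meta$sample_rate)

  fname <- filename_metadata(path)
  subject_id <- subject_id %||% meta$subject_id %||% fname$subject_id %||% "unknown"
  group <- group %||% meta$group %||% fname$group %||% "control"
  trial_index <- trial_index %||% meta$trial_index %||% fname$trial_index %||% 1L

  acc_scale <- if (dialect$acc_unit == "m/s2") 1 / G_MS2 else 1
  gyro_scale <- if (dialect$gyro_unit == "rad/s") 180 / pi else 1
  imu_recording(
    data.frame(
      acc_v = num[, "accV_g"] * acc_scale,
      acc_ml = num[, "accML_g"] * acc_scale,
      acc_ap = num[, "accAP_g"] * acc_scale,
      gyro_yaw = num[, "gyroYaw_dps"] * gyro_scale,
      gyro_pitch = num[, "gyroPitch_dps"] * gyro_scale,
      gyro_roll = num[, "gyroRoll_dps"] * gyro_scale
    ),
    sample_rate = sample_rate, subject_id = subject_id,
    group = match.arg(as.character(group), c("control", "PD")),
    trial_index = as.integer(trial_index)
  )
}

parse_sidecar <- function(lines, comment) {
  out <- list()
  for (ln in lines) {
    ln <- sub(paste0("^", comment, "\\s*"), "", ln)
    kv <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*:\\s*(.+)$", ln))[[1]]
    if (length(kv) == 3) out[[kv[[2]]]] <- trimws(kv[[3]])
  }
  if (!is.null(out$trial_index)) out$trial_index <- as.integer(out$trial_index)
  out
}

filename_metadata <- function(path) {
  base <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  m <- regmatches(base, regexec("^(.+)_(PD|control)_trial([0-9]+)$", base))[[1]]
  if (length(m) == 4) {
    list(subject_id = m[[2]], group = m[[3]], trial_index = as.integer(m[[4]]))
  } else {
    list()
  }
}

#' @rdname read_imu_recording
#' @param rec a validated [imu_recording].
#' @param digits significant digits written per value (round-trip precision).
#' @export
write_imu_recording <- function(rec, path, dialect = imu_dialect(), digits = 7) {
  stopifnot(inherits(rec, "imu_recording"))
  if (nrow(rec) < 1L) stop_fmt("value_error", "cannot write an empty recording")
  fmt_num <- function(x) {
    s <- formatC(x, digits = digits, format = "g")
    if (dialect$decimal_mark != ".") s <- gsub(".", dialect$decimal_mark, s, fixed = TRUE)
    s
  }
  cols <- list(
    accV_g = rec$acc_v, accML_g = rec$acc_ml, accAP_g = rec$acc_ap,
    gyroYaw_dps = rec$gyro_yaw, gyroPitch_dps = rec$gyro_pitch,
    gyroRoll_dps = rec$gyro_roll
  )
  if (dialect$time_column) cols <- c(list(time_s = rec$time_s), cols)
  mat <- vapply(cols, fmt_num, character(nrow(rec)))
  if (nrow(rec) == 1L) mat <- matrix(mat, nrow = 1, dimnames = list(NULL, names(cols)))
  lines <- c(
    paste0(dialect$comment, " subject_id: ", attr(rec, "subject_id")),
    paste0(dialect$comment, " group: ", attr(rec, "group")),
    paste0(dialect$comment, " trial_index: ", attr(rec, "trial_index")),
    paste0(dialect$comment, " sample_rate: ", format(attr(rec, "sample_rate"))),
    if (dialect$header) paste(names(cols), collapse = dialect$delimiter),
    apply(mat, 1, paste, collapse = dialect$delimiter)
  )
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_fmt("io_error", "cannot write to ", path)
  invisible(path)
}

#' Cohort manifests
#'
#' A manifest lists the recording files of a cohort together with subject
#' metadata and clinical scores (UPDRS III total and items, H&Y stage, FOG-Q,
#' MMSE). It is stored as YAML or JSON, chosen by file extension.
#'
#' @param manifest tibble with at least `subject_id`, `group`, `trial_index`
#'   and `path` columns; additional columns (clinical scores) pass through.
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @return `read_manifest()` returns a tibble; `write_manifest()` returns
#'   `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  recs <- purrr::transpose(as.list(manifest))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(list(recordings = recs), path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(recordings = recs), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    stop_fmt("value_error", "manifest path must end in .yaml, .yml or .json")
  }
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_fmt("io_error", "manifest not found: ", path)
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  if (is.null(obj$recordings)) stop_fmt("format_error", "manifest has no 'recordings' key")
  dplyr::bind_rows(lapply(obj$recordings, as_tibble))
}
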