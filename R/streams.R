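#' Body-worn accelerometer stream
#'
#' Container for one sensor's tri-axial acceleration time series together with
#' its placement metadata. Axis convention: `ax` mediolateral, `ay`
#' vertical/limb-longitudinal, `az` anteroposterior, all in m/s^2. The sensor
#' range is +/- 4 g; values outside it are rejected.
#'
#' @param patient_id Patient identifier (scalar, coerced to character).
#' @param placement `"thigh"` or `"upper_arm"`.
#' @param body_side `"left"` or `"right"`.
#' @param data `data.frame` with columns `time_s`, `ax`, `ay`, `az`;
#'   timestamps must be strictly increasing.
#' @param sampling_rate Nominal sampling rate in Hz (default 50).
#' @param role Side role relative to the hemiparesis, `"Aff"` or `"NonAff"`;
#'   usually assigned later by [assign_sides()].
#' @return An object of class `sensor_stream`.
#' @seealso [align_streams()], [assign_sides()], [window_features()]
#' @export
sensor_stream <- function(patient_id, placement, body_side, data,
                          sampling_rate = 50, role = NA_character_) {
  placement <- match.arg(placement, c("thigh", "upper_arm"))
  body_side <- match.arg(body_side, c("left", "right"))
  stopifnot(is.data.frame(data))
  need <- c("time_s", "ax", "ay", "az")
  if (!all(need %in% names(data))) {
    stop("stream data must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(data) > 1 && any(diff(data$time_s) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  g4 <- 4 * 9.80665
  acc <- as.matrix(data[, c("ax", "ay", "az")])
  if (any(abs(acc) > g4 + 1e-9, na.rm = TRUE)) {
    stop("acceleration outside the +/- 4 g sensor range")
  }
  structure(
    list(patient_id = as.character(patient_id), placement = placement,
         body_side = body_side, role = role,
         sampling_rate = sampling_rate,
         data = data[, need]),
    class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  dur <- if (nrow(x$data)) diff(range(x$data$time_s)) else 0
  cat(sprintf("<sensor_stream> patient %s, %s %s%s, %g Hz, %d samples (%.1f s)\n",
              x$patient_id, x$body_side, x$placement,
              if (!is.na(x$role)) paste0(" [", x$role, "]") else "",
              x$sampling_rate, nrow(x$data), dur))
  invisible(x)
}

#' Resample streams onto a shared uniform grid
#'
#' Time-synchronises a set of streams by linear interpolation onto one uniform
#' grid at the nominal sampling rate, covering only the time span where all
#' streams overlap. After alignment all streams have identical timestamps and
#' equal sample counts.
#'
#' @param streams List of [sensor_stream()] objects with equal nominal rates
#'   (mismatch above 1 \% is an error).
#' @return List of aligned `sensor_stream` objects.
#' @export
align_streams <- function(streams) {
  stopifnot(length(streams) >= 1)
  if (!all(vapply(streams, inherits, logical(1), "sensor_stream"))) {
    stop("all elements must be sensor_stream objects")
  }
  rates <- vapply(streams, function(s) s$sampling_rate, numeric(1))
  if (max(rates) / min(rates) > 1.01) stop("sampling rate mismatch above 1%")
  fs <- rates[[1]]
  t0 <- max(vapply(streams, function(s) min(s$data$time_s), numeric(1)))
  t1 <- min(vapply(streams, function(s) max(s$data$time_s), numeric(1)))
  if (t1 <= t0) stop("streams have no overlapping time span")
  grid <- seq(t0, t1, by = 1 / fs)
  lapply(streams, function(s) {
    d <- data.frame(time_s = grid)
    for (ax in c("ax", "ay", "az")) {
      d[[ax]] <- stats::approx(s$data$time_s, s$data[[ax]], xout = grid,
                               rule = 1)$y
    }
    s$data <- d
    s$sampling_rate <- fs
    s
  })
}

#' Relabel left/right streams as affected / non-affected
#'
#' @param streams List of [sensor_stream()] objects for one patient.
#' @param affected_side `"left"` or `"right"` - the hemiparetic side.
#' @return The streams with `role` set to `"Aff"` (sensor on the affected
#'   side) or `"NonAff"`.
#' @export
assign_sides <- function(streams, affected_side) {
  if (length(affected_side) != 1 || is.na(affected_side) ||
      !affected_side %in% c("left", "right")) {
    stop("affected_side must be \"left\" or \"right\"")
  }
  lapply(streams, function(s) {
    s$role <- if (s$body_side == affected_side) "Aff" else "NonAff"
    s
  })
}

#' Non-overlapping 1-s window features
#'
#' Partitions a stream into contiguous non-overlapping windows (1 s = 50
#' samples at the default rate) and computes the per-axis mean and population
#' variance of each full window. A trailing partial window is dropped.
#'
#' @param stream A [sensor_stream()], normally aligned first.
#' @param window_s Window length in seconds (default 1).
#' @return `data.frame` with one row per window: `window`, `t_start_s`,
#'   `mu_x`, `mu_y`, `mu_z`, `var_x`, `var_y`, `var_z`. Attributes `placement`,
#'   `role`, `sampling_rate` and `window_samples` carry the provenance that
#'   [walking_indicator()] checks.
#' @export
window_features <- function(stream, window_s = 1) {
  stopifnot(inherits(stream, "sensor_stream"))
  w <- round(stream$sampling_rate * window_s)
  n <- nrow(stream$data)
  k <- n %/% w
  feat <- data.frame(window = integer(0), t_start_s = numeric(0),
                     mu_x = numeric(0), mu_y = numeric(0), mu_z = numeric(0),
                     var_x = numeric(0), var_y = numeric(0), var_z = numeric(0))
  if (k >= 1) {
    idx <- seq_len(k * w)
    win_of <- rep(seq_len(k), each = w)
    stat1 <- function(v) {
      m <- matrix(v[idx], nrow = w)
      mu <- colMeans(m)
      va <- colMeans(m * m) - mu * mu  # population variance
      list(mu = mu, va = pmax(va, 0))
    }
    sx <- stat1(stream$data$ax); sy <- stat1(stream$data$ay)
    sz <- stat1(stream$data$az)
    feat <- data.frame(
      window = seq_len(k),
      t_start_s = stream$data$time_s[seq(1, k * w, by = w)],
      mu_x = sx$mu, mu_y = sy$mu, mu_z = sz$mu,
      var_x = sx$va, var_y = sy$va, var_z = sz$va)
  }
  attr(feat, "placement") <- stream$placement
  attr(feat, "role") <- stream$role
  attr(feat, "sampling_rate") <- stream$sampling_rate
  attr(feat, "window_samples") <- w
  feat
}

#' Read / write the per-sensor CSV dialect
#'
#' Plain CSV with a header row and columns `time_s, ax, ay, az` (m/s^2).
#'
#' @param path File path.
#' @param patient_id,placement,body_side,sampling_rate Stream metadata (reader).
#' @return `read_sensor_csv()` returns a [sensor_stream()];
#'   `write_sensor_csv()` returns `path` invisibly.
#' @export
read_sensor_csv <- function(path, patient_id, placement, body_side,
                            sampling_rate = 50) {
  d <- utils::read.csv(path)
  sensor_stream(patient_id, placement, body_side, d, sampling_rate)
}

#' @rdname read_sensor_csv
#' @param stream A [sensor_stream()] (writer).
#' @export
write_sensor_csv <- function(stream, path) {
  stopifnot(inherits(stream, "sensor_stream"))
  utils::write.csv(format_num_df(stream$data), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# fixed-format numbers so repeated writes are byte-identical
format_num_df <- function(d, digits = 6) {
  for (nm in names(d)) {
    if (is.numeric(d[[nm]])) d[[nm]] <- formatC(d[[nm]], digits = digits,
                                                format = "f")
  }
  d
}
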