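#' Cadence of a walking segment
#'
#' Cadence is strides per minute within a walking segment:
#' `C = n_strides / t_WS` with the segment duration in minutes. Note this
#' counts full strides, half the step-per-minute cadence used elsewhere.
#'
#' @param n_strides Stride count of one body side within the segment.
#' @param duration_s Segment duration in seconds (> 0).
#' @return Cadence in strides/min.
#' @export
cadence <- function(n_strides, duration_s) {
  if (any(duration_s <= 0)) stop("segment duration must be positive")
  n_strides / (duration_s / 60)
}

#' Per-stride arm sway
#'
#' Sway is the mean absolute mediolateral (x-axis) upper-arm acceleration over
#' the samples of one stride - the sum of positive samples plus the magnitude
#' of the sum of negative samples, divided by the sample count. Raw samples
#' are used; no detrending.
#'
#' @param x Mediolateral arm acceleration samples within the stride (at least
#'   2 samples).
#' @return Sway in m/s^2.
#' @export
sway <- function(x) {
  if (length(x) < 2) stop("a stride must contain at least 2 samples")
  mean(abs(x))
}

#' Sway of every stride in a sequence
#'
#' Looks up the side-matched upper-arm stream (affected arm for affected
#' strides) and computes [sway()] over each stride's sample span.
#'
#' @param sequence A `stride_sequence` with absolute stride times.
#' @param arm_streams List of aligned upper-arm [sensor_stream()]s with roles
#'   assigned.
#' @return The stride data.frame with a `sway` column appended.
#' @export
stride_sway <- function(sequence, arm_streams) {
  st <- sequence$strides
  st$sway <- NA_real_
  if (!nrow(st)) return(st)
  arms <- Filter(function(s) s$placement == "upper_arm", arm_streams)
  roles <- vapply(arms, function(s) s$role, character(1))
  for (i in seq_len(nrow(st))) {
    arm <- arms[[match(st$side[i], roles)]]
    sel <- arm$data$time_s >= st$start_s[i] & arm$data$time_s < st$end_s[i]
    if (sum(sel) >= 2) st$sway[i] <- sway(arm$data$ax[sel])
  }
  st
}

#' Daily movement-parameter summary
#'
#' Aggregates one recording day's accepted stride sequences into the per-side
#' daily parameters: total stride count, normalized stride count (strides per
#' hour of recording), and mean/SD of stride duration, cadence and sway.
#' Stride duration and sway statistics pool all strides; cadence is computed
#' per segment and averaged unweighted across segments. Days with zero strides
#' yield zero counts and `NA` (absent, not zero) means.
#'
#' @param strides `data.frame` with columns `side`, `duration_s`, `segment_id`,
#'   `segment_duration_s` and optionally `sway`; one row per stride. May have
#'   zero rows.
#' @param recording_h Recording span in hours (> 0).
#' @param patient_id,day Identifiers carried into the output.
#' @return `data.frame` with one row per body side (`Aff`, `NonAff`):
#'   `stride_count`, `stride_count_norm`, `dur_mean`, `dur_sd`, `cad_mean`,
#'   `cad_sd`, `sway_mean`, `sway_sd`, `recording_h`.
#' @export
daily_summary <- function(strides, recording_h, patient_id = NA, day = NA) {
  if (recording_h <= 0) stop("recording span must be positive")
  if (!"sway" %in% names(strides)) strides$sway <- NA_real_
  one_side <- function(role) {
    s <- strides[strides$side == role, , drop = FALSE]
    n <- nrow(s)
    if (n == 0) {
      return(data.frame(patient_id = patient_id, day = day, side = role,
                        stride_count = 0L, stride_count_norm = 0,
                        dur_mean = NA_real_, dur_sd = NA_real_,
                        cad_mean = NA_real_, cad_sd = NA_real_,
                        sway_mean = NA_real_, sway_sd = NA_real_,
                        recording_h = recording_h))
    }
    seg_cad <- vapply(split(s, s$segment_id), function(g)
      cadence(nrow(g), g$segment_duration_s[1]), numeric(1))
    data.frame(patient_id = patient_id, day = day, side = role,
               stride_count = n, stride_count_norm = n / recording_h,
               dur_mean = mean(s$duration_s), dur_sd = stats::sd(s$duration_s),
               cad_mean = mean(seg_cad), cad_sd = stats::sd(seg_cad),
               sway_mean = if (all(is.na(s$sway))) NA_real_
                           else mean(s$sway, na.rm = TRUE),
               sway_sd = if (all(is.na(s$sway))) NA_real_
                         else stats::sd(s$sway[!is.na(s$sway)]),
               recording_h = recording_h)
  }
  out <- rbind(one_side("Aff"), one_side("NonAff"))
  row.names(out) <- NULL
  out
}
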