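#' Pipeline configuration
#'
#' Collects every tunable of the four analysis stages with defaults equal to
#' the published values where one exists: walking thresholds theta1 = 8,
#' theta2 = 4, theta3 = 0.7 (walker) / 0.25 (wheelchair), 1-s windows,
#' stride-duration bounds [0.25, 3] s, minimum 5 consecutive strides,
#' convergence cut-off t_max = 3650 days.
#'
#' @param theta1,theta2,theta3_walker,theta3_wheelchair Walking-rule
#'   thresholds.
#' @param window_s Analysis window length, s.
#' @param stride_bounds_s Admissible stride duration, s.
#' @param median_kernel Median smoothing kernel, samples.
#' @param ac_threshold Periodicity-filter acceptance threshold.
#' @param min_strides Minimum consecutive in-bounds non-affected strides.
#' @param min_peak_separation_s Minimum peak spacing, s.
#' @param peak_amp_quantile,peak_amp_frac Peak amplitude-threshold parameters.
#' @param t_max Convergence cut-off, days.
#' @param exclude_physio Mask walking segments recorded during physiotherapy.
#' @param exclude_labels Annotation labels masked when `exclude_physio`.
#' @param sampling_rate Hz.
#' @param trend_parameters Daily parameters to trend-analyse.
#' @param seed Seed recorded for provenance (the analysis itself is
#'   deterministic).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(theta1 = 8, theta2 = 4, theta3_walker = 0.7,
                            theta3_wheelchair = 0.25, window_s = 1,
                            stride_bounds_s = c(0.25, 3), median_kernel = 5,
                            ac_threshold = 0.3, min_strides = 5,
                            min_peak_separation_s = 0.25,
                            peak_amp_quantile = 0.95, peak_amp_frac = 0.3,
                            t_max = 3650, exclude_physio = TRUE,
                            exclude_labels = "physiotherapy_walk",
                            sampling_rate = 50,
                            trend_parameters = c("stride_count_norm",
                                                 "dur_mean", "cad_mean",
                                                 "sway_mean"),
                            seed = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Process one recording day end to end
#'
#' Stages 1-3 for a single day: alignment, side labelling, window features of
#' the non-affected thigh, the walking rule, segment formation, the
#' physiotherapy exclusion mask, per-segment stride segmentation, per-stride
#' sway, and the daily summary.
#'
#' @param streams List of the day's four [sensor_stream()]s (two thighs, two
#'   upper arms).
#' @param affected_side `"left"` or `"right"`.
#' @param locomotion_type `"walker"` or `"wheelchair"` (selects theta3).
#' @param config A [pipeline_config()].
#' @param annotations Optional annotation `data.frame` (`start_s`, `end_s`,
#'   `label`) for the exclusion mask.
#' @param patient_id,day Identifiers carried into outputs.
#' @return List: `daily` (per-side [daily_summary()] rows), `strides` (stride
#'   table), `segments` (detected walking segments incl. masked ones),
#'   `rejections` (`segment_id`, `reason`), `flags`.
#' @export
process_recording_day <- function(streams, affected_side, locomotion_type,
                                  config = pipeline_config(),
                                  annotations = NULL, patient_id = NA,
                                  day = NA) {
  placements <- vapply(streams, function(s) s$placement, character(1))
  for (need in c("thigh", "upper_arm")) {
    if (sum(placements == need) != 2) {
      stop("manifest must provide exactly two ", need, " sensors")
    }
  }
  aligned <- assign_sides(align_streams(streams), affected_side)
  roles <- vapply(aligned, function(s) s$role, character(1))
  placements <- vapply(aligned, function(s) s$placement, character(1))
  thigh <- list(Aff = aligned[[which(placements == "thigh" &
                                       roles == "Aff")]],
                NonAff = aligned[[which(placements == "thigh" &
                                          roles == "NonAff")]])
  arms <- aligned[placements == "upper_arm"]

  th <- walking_thresholds(locomotion_type, theta1 = config$theta1,
                           theta2 = config$theta2,
                           theta3 = if (locomotion_type == "wheelchair")
                             config$theta3_wheelchair else
                               config$theta3_walker)
  feats <- window_features(thigh$NonAff, config$window_s)
  flags <- walking_indicator(feats, th)
  w <- attr(feats, "window_samples")
  segments <- windows_to_segments(flags, w, config$sampling_rate)
  kept_segments <- if (config$exclude_physio) {
    # annotation times are absolute; the aligned grid may start later
    ann_rel <- annotations
    if (!is.null(ann_rel)) {
      t0 <- thigh$NonAff$data$time_s[1]
      ann_rel$start_s <- ann_rel$start_s - t0
      ann_rel$end_s <- ann_rel$end_s - t0
    }
    apply_exclusions(segments, ann_rel, config$exclude_labels)
  } else segments

  stride_rows <- list(); rejections <- list()
  for (i in seq_len(nrow(kept_segments))) {
    sg <- kept_segments[i, ]
    idx <- (sg$start_sample + 1L):sg$end_sample
    sq <- strides_from_segment(
      thigh$NonAff$data$ay[idx], thigh$Aff$data$ay[idx],
      sampling_rate = config$sampling_rate,
      t_offset_s = thigh$NonAff$data$time_s[sg$start_sample + 1L],
      median_kernel = config$median_kernel,
      ac_threshold = config$ac_threshold,
      stride_bounds_s = config$stride_bounds_s,
      min_strides = config$min_strides,
      min_separation_s = config$min_peak_separation_s,
      amp_quantile = config$peak_amp_quantile,
      amp_frac = config$peak_amp_frac,
      segment_id = sg$segment_id)
    if (!sq$accepted) {
      rejections[[length(rejections) + 1L]] <-
        data.frame(segment_id = sg$segment_id, reason = sq$reason)
      next
    }
    st <- stride_sway(sq, arms)
    st$segment_id <- sg$segment_id
    st$segment_duration_s <- sg$duration_s
    stride_rows[[length(stride_rows) + 1L]] <- st
  }
  strides <- if (length(stride_rows)) do.call(rbind, stride_rows) else
    data.frame(side = character(0), start_s = numeric(0), end_s = numeric(0),
               duration_s = numeric(0), sway = numeric(0),
               segment_id = integer(0), segment_duration_s = numeric(0))
  recording_h <- nrow(thigh$NonAff$data) / config$sampling_rate / 3600
  daily <- daily_summary(strides, recording_h, patient_id, day)
  list(daily = daily, strides = strides, segments = segments,
       rejections = if (length(rejections)) do.call(rbind, rejections) else
         data.frame(segment_id = integer(0), reason = character(0)),
       flags = flags)
}

#' Run the full pipeline from a directory of per-sensor CSVs
#'
#' Reads `patients.csv` (`patient_id`, `affected_side`, `locomotion_type`)
#' and `manifest.csv` (`patient_id`, `day`, `placement`, `body_side`, `file`,
#' optional `annotations`) from `input_dir`, processes every recording day
#' (stages 1-3) and fits the per-patient recovery trends (stage 4). Outputs
#' are written atomically; rerunning with an identical configuration yields
#' byte-identical files.
#'
#' @param input_dir Directory with the manifest and sensor CSVs (the dialect
#'   [write_recording_day()] emits).
#' @param out_dir Output directory: `daily_parameters.csv`,
#'   `stride_table.csv`, `trend_report.json`.
#' @param config A [pipeline_config()].
#' @return Invisibly, list with `daily` (all days/sides) and `trends` (per
#'   patient [trend_report()]).
#' @export
run_pipeline <- function(input_dir, out_dir, config = pipeline_config()) {
  patients <- utils::read.csv(file.path(input_dir, "patients.csv"))
  manifest <- utils::read.csv(file.path(input_dir, "manifest.csv"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  daily_all <- list(); strides_all <- list(); trends <- list()
  any_walking <- FALSE
  for (pid in unique(patients$patient_id)) {
    pinfo <- patients[patients$patient_id == pid, ][1, ]
    pm <- manifest[manifest$patient_id == pid, ]
    for (d in sort(unique(pm$day))) {
      dm <- pm[pm$day == d, ]
      for (need in c("thigh", "upper_arm")) {
        if (sum(dm$placement == need) != 2) {
          stop("patient ", pid, " day ", d, ": manifest is missing a ",
               need, " sensor")
        }
      }
      streams <- lapply(seq_len(nrow(dm)), function(i)
        read_sensor_csv(file.path(input_dir, dm$file[i]), pid,
                        dm$placement[i], dm$body_side[i],
                        config$sampling_rate))
      ann <- NULL
      if ("annotations" %in% names(dm) && nzchar(dm$annotations[1]) &&
          file.exists(file.path(input_dir, dm$annotations[1]))) {
        ann <- utils::read.csv(file.path(input_dir, dm$annotations[1]))
      }
      res <- process_recording_day(streams, pinfo$affected_side,
                                   pinfo$locomotion_type, config, ann,
                                   patient_id = pid, day = d)
      daily_all[[length(daily_all) + 1L]] <- res$daily
      if (nrow(res$strides)) {
        st <- res$strides
        st$patient_id <- pid; st$day <- d
        strides_all[[length(strides_all) + 1L]] <- st
        any_walking <- TRUE
      }
    }
    pd <- do.call(rbind, daily_all)
    pd <- pd[pd$patient_id == pid, ]
    if (nrow(pd) && any(pd$stride_count > 0)) {
      trends[[as.character(pid)]] <-
        trend_report(pd, config$trend_parameters, config$t_max)
    } else {
      trends[[as.character(pid)]] <- list()
    }
  }
  if (!any_walking) warning("no walking detected on any day")

  daily <- do.call(rbind, daily_all)
  strides <- if (length(strides_all)) do.call(rbind, strides_all) else
    data.frame()
  write_atomic <- function(obj, file, writer) {
    tmp <- paste0(file, ".tmp")
    writer(obj, tmp)
    file.rename(tmp, file)
  }
  write_atomic(daily, file.path(out_dir, "daily_parameters.csv"),
               function(o, f) utils::write.csv(format_num_df(o), f,
                                               row.names = FALSE,
                                               quote = FALSE))
  write_atomic(strides, file.path(out_dir, "stride_table.csv"),
               function(o, f) utils::write.csv(format_num_df(o), f,
                                               row.names = FALSE,
                                               quote = FALSE))
  write_atomic(lapply(trends, function(tr) lapply(tr, function(e) {
    if (is.list(e) && !is.null(e$continuous)) {
      e$continuous <- as.list(e$continuous)
    }
    e
  })), file.path(out_dir, "trend_report.json"),
  function(o, f) jsonlite::write_json(o, f, auto_unbox = TRUE, digits = 8,
                                      na = "null"))
  invisible(list(daily = daily, trends = trends))
}
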