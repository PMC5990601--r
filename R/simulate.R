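#' Gait profile for the synthetic recording generator
#'
#' Describes the per-side gait of one simulated patient. Defaults reflect a
#' typical hemiparetic walker: per-side mean stride durations near 1.4 s,
#' reduced dynamic acceleration on the affected thigh
#' (`amplitude_asymmetry`), and larger mediolateral arm sway on the affected
#' side. `sway_amp_*` are sinusoid amplitudes of the upper-arm mediolateral
#' axis; the analytic per-stride sway of such an oscillation is `2 * A / pi`.
#'
#' @param stride_duration_mean_aff,stride_duration_mean_nonaff Mean stride
#'   duration per side in seconds, within [0.25, 3].
#' @param stride_duration_sd Stride-to-stride jitter SD in seconds (truncated
#'   normal, kept within [0.25, 3]).
#' @param amplitude_asymmetry Scale in (0, 1] applied to the affected thigh's
#'   dynamic component.
#' @param sway_amp_aff,sway_amp_nonaff Arm-sway sinusoid amplitudes, m/s^2.
#' @param locomotion_type `"walker"` or `"wheelchair"`. Wheelchair users walk
#'   with a gentler vertical oscillation, which is why their walking-rule
#'   variance threshold is lower.
#' @param affected_side `"left"` or `"right"`.
#' @param phase_lag Fraction of a stride by which the affected grid lags the
#'   non-affected one (default 0: both sides share the stride grid, so that
#'   per-side true stride counts equal `floor(bout / stride_duration)`).
#' @param noise_sd Additive white accelerometer noise SD, m/s^2.
#' @return List of class `gait_profile`.
#' @export
gait_profile <- function(stride_duration_mean_aff = 1.40,
                         stride_duration_mean_nonaff = 1.38,
                         stride_duration_sd = 0,
                         amplitude_asymmetry = 0.7,
                         sway_amp_aff = 3.7, sway_amp_nonaff = 1.8,
                         locomotion_type = c("walker", "wheelchair"),
                         affected_side = c("left", "right"),
                         phase_lag = 0, noise_sd = 0.05) {
  locomotion_type <- match.arg(locomotion_type)
  affected_side <- match.arg(affected_side)
  durs <- c(stride_duration_mean_aff, stride_duration_mean_nonaff)
  if (any(durs < 0.25 | durs > 3)) {
    stop("stride duration means must lie within [0.25, 3] s")
  }
  if (amplitude_asymmetry <= 0 || amplitude_asymmetry > 1) {
    stop("amplitude_asymmetry must be in (0, 1]")
  }
  if (sway_amp_aff < 0 || sway_amp_nonaff < 0 || stride_duration_sd < 0 ||
      noise_sd < 0) {
    stop("amplitudes and noise/jitter SDs must be non-negative")
  }
  structure(list(
    stride_duration_mean_aff = stride_duration_mean_aff,
    stride_duration_mean_nonaff = stride_duration_mean_nonaff,
    stride_duration_sd = stride_duration_sd,
    amplitude_asymmetry = amplitude_asymmetry,
    sway_amp_aff = sway_amp_aff, sway_amp_nonaff = sway_amp_nonaff,
    locomotion_type = locomotion_type, affected_side = affected_side,
    phase_lag = phase_lag, noise_sd = noise_sd),
    class = "gait_profile")
}

#' Day script for the synthetic recording generator
#'
#' An ordered list of activity bouts that make up one simulated recording day.
#'
#' @param bouts `data.frame` with columns `activity` (one of `walk`, `sit`,
#'   `stand`, `wheelchair_propel`, `physiotherapy_walk`) and `duration_s`
#'   (> 0; every bout must span at least one 1-s analysis window).
#' @param sampling_rate Hz, default 50.
#' @param seed Integer RNG seed.
#' @param day_index Recording day index; the day's RNG stream is derived from
#'   `(seed, day_index)` so individual days reproduce independently.
#' @return List of class `day_script`.
#' @export
day_script <- function(bouts, sampling_rate = 50, seed = 1, day_index = 1) {
  stopifnot(is.data.frame(bouts),
            all(c("activity", "duration_s") %in% names(bouts)))
  acts <- c("walk", "sit", "stand", "wheelchair_propel", "physiotherapy_walk")
  if (!all(bouts$activity %in% acts)) {
    stop("unknown activity; allowed: ", paste(acts, collapse = ", "))
  }
  if (any(bouts$duration_s <= 0)) stop("bout durations must be positive")
  if (any(bouts$duration_s < 1)) {
    stop("bout shorter than one 1-s analysis window")
  }
  structure(list(bouts = bouts, sampling_rate = sampling_rate,
                 seed = as.integer(seed), day_index = as.integer(day_index)),
            class = "day_script")
}

#' A plausible rehabilitation day-care schedule
#'
#' Convenience script: sitting, standing and several multi-minute walking
#' bouts (plus wheelchair propulsion for wheelchair users), roughly one hour
#' in total.
#'
#' @param seed,day_index Passed to [day_script()].
#' @param locomotion_type Adds propulsion bouts for `"wheelchair"`.
#' @return A [day_script()].
#' @export
example_day_script <- function(seed = 1, day_index = 1,
                               locomotion_type = c("walker", "wheelchair")) {
  locomotion_type <- match.arg(locomotion_type)
  roll <- if (locomotion_type == "wheelchair") "wheelchair_propel" else "sit"
  bouts <- data.frame(
    activity = c("sit", "walk", "stand", roll, "walk", "sit",
                 "physiotherapy_walk", roll, "walk", "sit"),
    duration_s = c(300, 120, 60, 240, 90, 300, 120, 180, 150, 240))
  day_script(bouts, seed = seed, day_index = day_index)
}

# ---- internal signal constants ------------------------------------------
.sig <- list(
  g_upright = 9.4,      # gravity-dominated vertical baseline, thigh upright
  g_seated = 2.0,       # vertical thigh mean when seated
  pulse_amp = 6,        # non-affected stride pulse amplitude, m/s^2
  pulse_tau = 0.12,     # pulse decay time constant, s
  osc_walker = 1.8,     # vertical walking oscillation amplitude, walker
  osc_wheelchair = 1.1) # gentler oscillation for wheelchair users' walking

# exponential-onset pulse train added at the true stride boundaries; the
# dominant acceleration maximum and the derivative maximum coincide at onset
add_pulses <- function(sig, t, boundaries, amp, tau = .sig$pulse_tau) {
  for (tb in boundaries) {
    i0 <- findInterval(tb - 1e-9, t) + 1L
    i1 <- min(length(t), i0 + ceiling(0.6 * 50))
    if (i0 > length(t)) next
    idx <- i0:i1
    sig[idx] <- sig[idx] + amp * exp(-pmax(0, t[idx] - tb) / tau)
  }
  sig
}

# gait-cycle phase locked to the true stride boundaries: each stride spans
# exactly one 2*pi cycle, so oscillation extrema coincide with the boundary
# pulses even under stride-time jitter
stride_phase <- function(tt, boundaries, d_mean) {
  nb <- length(boundaries)
  if (nb < 2) return(2 * pi * (tt - boundaries[1]) / d_mean)
  k <- pmin(pmax(findInterval(tt, boundaries), 1L), nb - 1L)
  u <- (tt - boundaries[k]) / (boundaries[k + 1L] - boundaries[k])
  2 * pi * ((k - 1L) + u)
}

# truncated-normal stride durations accumulated over a bout
draw_boundaries <- function(t0, dur, d_mean, d_sd) {
  if (d_sd == 0) {
    n <- floor(dur / d_mean + 1e-9)
    if (n < 1) stop("zero-stride walk bout: bout shorter than one stride")
    return(t0 + (0:n) * d_mean)
  }
  b <- t0
  repeat {
    d <- stats::rnorm(1, d_mean, d_sd)
    while (d < 0.25 || d > 3) d <- stats::rnorm(1, d_mean, d_sd)
    nxt <- b[length(b)] + d
    if (nxt > t0 + dur + 1e-9) break
    b <- c(b, nxt)
  }
  if (length(b) < 2) stop("zero-stride walk bout: bout shorter than one stride")
  b
}

#' Simulate one recording day with ground truth
#'
#' Generates the four tri-axial sensor streams (both thighs, both upper arms)
#' for a scripted day, alongside the ground truth the validation needs. During
#' walking the non-affected thigh's vertical axis carries a gravity-dominated
#' baseline, a stride-frequency oscillation and one dominant exponential-onset
#' pulse per true stride, so the 1-s window features satisfy the walking rule;
#' sitting violates it through a low vertical mean, standing through a low
#' variance, and wheelchair propulsion through a low vertical mean. The
#' upper-arm mediolateral axis oscillates sinusoidally with the side's sway
#' amplitude while walking. Identical `(profile, script)` inputs (including
#' the script's seed) reproduce the streams bit for bit.
#'
#' @param profile A [gait_profile()].
#' @param script A [day_script()].
#' @return List of class `recording_day`: `streams` (named list
#'   `thigh_left`, `thigh_right`, `arm_left`, `arm_right`), `truth` (walking
#'   intervals in samples/seconds, per-side true stride boundary times,
#'   per-side analytic per-stride sway), `annotations` (`start_s`, `end_s`,
#'   `label` for every bout), `profile`, `script`.
#' @export
simulate_recording_day <- function(profile, script) {
  stopifnot(inherits(profile, "gait_profile"), inherits(script, "day_script"))
  set.seed((script$seed %% 1000003L) + 100003L * (script$day_index %% 1000L))
  fs <- script$sampling_rate
  bouts <- script$bouts
  total <- sum(bouts$duration_s)
  n <- round(total * fs)
  t <- (seq_len(n) - 1) / fs

  osc_amp <- if (profile$locomotion_type == "wheelchair")
    .sig$osc_wheelchair else .sig$osc_walker
  amp <- list(Aff = .sig$pulse_amp * profile$amplitude_asymmetry,
              NonAff = .sig$pulse_amp)
  sway_amp <- list(Aff = profile$sway_amp_aff,
                   NonAff = profile$sway_amp_nonaff)
  d_mean <- list(Aff = profile$stride_duration_mean_aff,
                 NonAff = profile$stride_duration_mean_nonaff)

  ax <- list()  # [sensor][axis] sample vectors
  for (s in c("thigh_Aff", "thigh_NonAff", "arm_Aff", "arm_NonAff")) {
    ax[[s]] <- list(x = numeric(n), y = numeric(n), z = numeric(n))
  }
  truth_bound <- list(Aff = numeric(0), NonAff = numeric(0))
  truth_sway <- list(Aff = numeric(0), NonAff = numeric(0))
  walk_iv <- data.frame(start_sample = integer(0), end_sample = integer(0),
                        start_s = numeric(0), end_s = numeric(0),
                        activity = character(0))
  ann <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    label = character(0))

  b0 <- 0
  for (bi in seq_len(nrow(bouts))) {
    act <- bouts$activity[bi]; dur <- bouts$duration_s[bi]
    i0 <- round(b0 * fs) + 1L; i1 <- round((b0 + dur) * fs)
    idx <- i0:i1; tb <- t[idx]
    ann <- rbind(ann, data.frame(start_s = b0, end_s = b0 + dur, label = act))

    if (act %in% c("walk", "physiotherapy_walk")) {
      walk_iv <- rbind(walk_iv, data.frame(
        start_sample = i0 - 1L, end_sample = i1, start_s = b0,
        end_s = b0 + dur, activity = act))
      for (role in c("NonAff", "Aff")) {
        lag <- if (role == "Aff") profile$phase_lag * d_mean[[role]] else 0
        bnd <- draw_boundaries(b0 + lag, dur - lag, d_mean[[role]],
                               profile$stride_duration_sd)
        truth_bound[[role]] <- c(truth_bound[[role]], bnd)
        truth_sway[[role]] <- c(truth_sway[[role]],
                                rep(2 * sway_amp[[role]] / pi,
                                    length(bnd) - 1))
        th <- paste0("thigh_", role); arm <- paste0("arm_", role)
        ph <- stride_phase(tb, bnd, d_mean[[role]])
        ax[[th]]$y[idx] <- .sig$g_upright + osc_amp * sin(ph)
        ax[[th]]$y <- add_pulses(ax[[th]]$y, t, bnd, amp[[role]])
        ax[[th]]$z[idx] <- 1.5 + 0.4 * sin(2 * ph)
        ax[[th]]$x[idx] <- 0.3 * sin(ph + pi / 3)
        ax[[arm]]$x[idx] <- sway_amp[[role]] * sin(ph)
        ax[[arm]]$y[idx] <- .sig$g_upright
        ax[[arm]]$z[idx] <- 0.5
      }
    } else if (act == "sit") {
      for (role in c("NonAff", "Aff")) {
        ax[[paste0("thigh_", role)]]$y[idx] <- .sig$g_seated
        ax[[paste0("thigh_", role)]]$z[idx] <- 9.3
        ax[[paste0("arm_", role)]]$y[idx] <- .sig$g_upright
      }
    } else if (act == "stand") {
      for (role in c("NonAff", "Aff")) {
        ax[[paste0("thigh_", role)]]$y[idx] <- .sig$g_upright
        ax[[paste0("thigh_", role)]]$z[idx] <- 1.0
        ax[[paste0("arm_", role)]]$y[idx] <- .sig$g_upright
      }
    } else if (act == "wheelchair_propel") {
      # stipulated model: seated thigh, rhythmic arm push at ~1 Hz
      for (role in c("NonAff", "Aff")) {
        ph <- 2 * pi * 1.0 * (tb - b0)
        th <- paste0("thigh_", role); arm <- paste0("arm_", role)
        ax[[th]]$y[idx] <- 2.5 + 0.3 * sin(ph)
        ax[[th]]$z[idx] <- 9.2
        ax[[arm]]$x[idx] <- 2.0 * sin(ph)
        ax[[arm]]$y[idx] <- 6.0 + 1.5 * sin(ph + pi / 4)
        ax[[arm]]$z[idx] <- 3.0
      }
    }
    b0 <- b0 + dur
  }

  g4 <- 4 * 9.80665
  streams <- list()
  side_of <- function(role) {
    if (role == "Aff") profile$affected_side
    else setdiff(c("left", "right"), profile$affected_side)
  }
  for (s in c("thigh_Aff", "thigh_NonAff", "arm_Aff", "arm_NonAff")) {
    placement <- if (startsWith(s, "thigh")) "thigh" else "upper_arm"
    role <- sub(".*_", "", s)
    d <- data.frame(time_s = t)
    for (axis in c("x", "y", "z")) {
      v <- ax[[s]][[axis]] + stats::rnorm(n, 0, profile$noise_sd)
      d[[paste0("a", axis)]] <- pmin(pmax(v, -g4), g4)
    }
    key <- paste0(if (placement == "thigh") "thigh_" else "arm_",
                  side_of(role))
    streams[[key]] <- sensor_stream("sim", placement, side_of(role), d,
                                    sampling_rate = fs, role = role)
  }
  streams <- streams[c(paste0("thigh_", c("left", "right")),
                       paste0("arm_", c("left", "right")))]

  structure(list(
    streams = streams,
    truth = list(walking = walk_iv,
                 stride_times = truth_bound,
                 stride_sway = truth_sway),
    annotations = ann, profile = profile, script = script),
    class = "recording_day")
}

#' @export
print.recording_day <- function(x, ...) {
  cat(sprintf(
    "<recording_day> %s, day %d, %.0f s, %d walk bouts, %d/%d true strides (NonAff/Aff)\n",
    x$profile$locomotion_type, x$script$day_index,
    sum(x$script$bouts$duration_s), nrow(x$truth$walking),
    max(0, length(x$truth$stride_times$NonAff) - nrow(x$truth$walking)),
    max(0, length(x$truth$stride_times$Aff) - nrow(x$truth$walking))))
  invisible(x)
}

#' Simulate per-side daily parameter series with linear trends
#'
#' Draws `value_side(t) = alpha_side + beta_side * t + eps`,
#' `eps ~ N(0, noise_sd^2)` independently per day and side, and returns the
#' analytic convergence point of the two noiseless lines.
#'
#' @param alpha_aff,alpha_nonaff Offsets (parameter units).
#' @param beta_aff,beta_nonaff Slopes (units/day).
#' @param noise_sd Daily noise SD (>= 0).
#' @param n_days Number of recording days (>= 2).
#' @param day_indices Days since study begin (default `1:n_days`).
#' @param seed RNG seed.
#' @return List of class `parameter_series`: `series` (`data.frame` with
#'   `day`, `aff`, `nonaff`), `cp_analytic` (days; `NA` when parallel),
#'   `parallel` flag, and the generating coefficients.
#' @export
simulate_parameter_series <- function(alpha_aff, alpha_nonaff, beta_aff,
                                      beta_nonaff, noise_sd = 0, n_days = 30,
                                      day_indices = seq_len(n_days),
                                      seed = 1) {
  if (n_days < 2 || length(day_indices) < 2) {
    stop("need at least 2 recording days")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(seed)
  tt <- day_indices
  aff <- alpha_aff + beta_aff * tt + stats::rnorm(length(tt), 0, noise_sd)
  nonaff <- alpha_nonaff + beta_nonaff * tt +
    stats::rnorm(length(tt), 0, noise_sd)
  parallel <- (beta_aff == beta_nonaff)
  cp <- if (parallel) NA_real_
        else (alpha_aff - alpha_nonaff) / (beta_nonaff - beta_aff)
  structure(list(series = data.frame(day = tt, aff = aff, nonaff = nonaff),
                 cp_analytic = cp, parallel = parallel,
                 coef = list(alpha_aff = alpha_aff, alpha_nonaff = alpha_nonaff,
                             beta_aff = beta_aff, beta_nonaff = beta_nonaff,
                             noise_sd = noise_sd)),
            class = "parameter_series")
}

#' Write a simulated day in the pipeline's CSV dialect
#'
#' Writes the four per-sensor CSVs, a ground-truth annotation CSV
#' (`start_s`, `end_s`, `label`) and a JSON sidecar with the true stride
#' times, and returns the manifest rows describing the files.
#'
#' @param day A [simulate_recording_day()] result.
#' @param dir Output directory (created if needed).
#' @param patient_id,day_index Identifiers used in file names.
#' @return `data.frame` of manifest rows (`patient_id`, `day`, `placement`,
#'   `body_side`, `file`), invisibly used by [run_pipeline()].
#' @export
write_recording_day <- function(day, dir, patient_id = "sim", day_index = 1) {
  stopifnot(inherits(day, "recording_day"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (key in names(day$streams)) {
    s <- day$streams[[key]]
    f <- sprintf("%s_d%02d_%s_%s.csv", patient_id, day_index, s$placement,
                 s$body_side)
    write_sensor_csv(s, file.path(dir, f))
    rows[[key]] <- data.frame(patient_id = patient_id, day = day_index,
                              placement = s$placement,
                              body_side = s$body_side, file = f)
  }
  ann_file <- sprintf("%s_d%02d_annotations.csv", patient_id, day_index)
  utils::write.csv(format_num_df(day$annotations, 3),
                   file.path(dir, ann_file), row.names = FALSE, quote = FALSE)
  truth_file <- sprintf("%s_d%02d_truth.json", patient_id, day_index)
  jsonlite::write_json(day$truth, file.path(dir, truth_file),
                       auto_unbox = TRUE, digits = NA)
  manifest <- do.call(rbind, rows)
  manifest$annotations <- ann_file
  row.names(manifest) <- NULL
  manifest
}
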