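#' Autocorrelation periodicity filter
#'
#' Walking is periodic at the stride time scale. A candidate segment is kept
#' iff the normalised autocorrelation of its mean-removed vertical thigh
#' signal has a maximum of at least `threshold` over lags spanning the
#' admissible stride durations (0.25-3 s). Segments shorter than 2 s or with
#' zero variance are rejected.
#'
#' @param y Vertical-axis thigh acceleration of the segment (non-affected
#'   side), numeric vector.
#' @param sampling_rate Hz.
#' @param lag_range_s Lag window in seconds, default `c(0.25, 3)`.
#' @param threshold Acceptance threshold on the autocorrelation peak.
#' @return `TRUE` (keep) or `FALSE` (reject) with attribute `reason` on
#'   rejection.
#' @export
periodicity_filter <- function(y, sampling_rate = 50,
                               lag_range_s = c(0.25, 3), threshold = 0.3) {
  n <- length(y)
  if (n < 2 * sampling_rate) {
    return(structure(FALSE, reason = "too_short"))
  }
  if (stats::var(y) == 0) {
    return(structure(FALSE, reason = "zero_variance"))
  }
  lmin <- max(1L, ceiling(lag_range_s[1] * sampling_rate))
  lmax <- min(n - 1L, floor(lag_range_s[2] * sampling_rate))
  ac <- stats::acf(y - mean(y), lag.max = lmax, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  peak <- max(ac[(lmin:lmax) + 1L])
  if (peak >= threshold) TRUE else structure(FALSE, reason = "aperiodic")
}

# median smoothing + central-difference derivative, the signal conditioning
# shared by both thighs before peak detection
smooth_derivative <- function(y, sampling_rate = 50, median_kernel = 5) {
  if (length(y) >= median_kernel) {
    y <- stats::runmed(y, k = median_kernel, endrule = "median")
  }
  n <- length(y)
  d <- numeric(n)
  if (n >= 3) {
    d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) * sampling_rate / 2
    d[1] <- (y[2] - y[1]) * sampling_rate
    d[n] <- (y[n] - y[n - 1]) * sampling_rate
  } else if (n == 2) {
    d[] <- (y[2] - y[1]) * sampling_rate
  }
  as.numeric(d)
}

#' Hill-climb peak detection on the acceleration derivative
#'
#' Seeds every sample whose derivative exceeds the amplitude threshold
#' (`amp_frac` times the segment's `amp_quantile` quantile of the absolute
#' derivative) and iteratively climbs each seed to its nearest local maximum.
#' Surviving peaks are deduplicated and a minimum separation of
#' `min_separation_s` is enforced, keeping the higher peak (earlier on ties).
#'
#' @param d Derivative signal (from [smooth_derivative()]).
#' @param sampling_rate Hz.
#' @param min_separation_s Minimum peak spacing in seconds (default 0.25, the
#'   shortest admissible stride).
#' @param amp_quantile,amp_frac Amplitude-threshold parameters (defaults 0.95
#'   and 0.3).
#' @return Integer vector of peak sample indices (1-based, ordered). Empty for
#'   flat signals.
#' @export
hill_climb_peaks <- function(d, sampling_rate = 50, min_separation_s = 0.25,
                             amp_quantile = 0.95, amp_frac = 0.3) {
  n <- length(d)
  if (n < 2 || diff(range(d)) == 0) return(integer(0))
  thr <- amp_frac * stats::quantile(abs(d), amp_quantile, names = FALSE)
  seeds <- which(d >= thr & d > 0)
  if (!length(seeds)) return(integer(0))
  climb <- function(i) {
    repeat {
      nb <- c(if (i > 1) i - 1L, if (i < n) i + 1L)
      up <- nb[d[nb] > d[i]]
      if (!length(up)) return(i)
      i <- up[which.max(d[up])]
    }
  }
  peaks <- unique(vapply(seeds, climb, integer(1)))
  # greedy non-maximum suppression: strongest first, earlier index on ties
  ord <- order(-d[peaks], peaks)
  peaks <- peaks[ord]
  min_gap <- round(min_separation_s * sampling_rate)
  kept <- integer(0)
  for (p in peaks) {
    if (!length(kept) || all(abs(kept - p) >= min_gap)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Bilateral stride verification
#'
#' Anchors strides on the non-affected thigh (the higher-amplitude signal):
#' non-affected strides are the intervals between its consecutive peaks. For
#' every such interval exactly one affected-side peak is kept - the maximum of
#' the affected derivative within the interval; surplus affected candidates
#' are dropped. One trailing affected peak after the last non-affected peak
#' may form one extra affected stride, so the per-segment counts differ by at
#' most one. The final affected stride is closed at its peak plus the last
#' non-affected interval's duration.
#'
#' @param peaks_nonaff Non-affected peak sample indices (needs at least 2).
#' @param d_aff Affected-side derivative signal on the same sample grid.
#' @param sampling_rate Hz.
#' @param aff_candidates Optional detected affected peak indices; where an
#'   interval contains none, the within-interval argmax of `d_aff` is used.
#' @param t_offset_s Absolute time of the segment's first sample.
#' @return Object of class `stride_sequence`: list with `strides` (data.frame
#'   `side`, `start_s`, `end_s`, `duration_s`), and per-side peak indices.
#' @export
pair_bilateral_strides <- function(peaks_nonaff, d_aff, sampling_rate = 50,
                                   aff_candidates = NULL, t_offset_s = 0) {
  empty <- new_stride_sequence(
    data.frame(side = character(0), start_s = numeric(0), end_s = numeric(0),
               duration_s = numeric(0)),
    peaks_nonaff = integer(0), peaks_aff = integer(0))
  if (length(peaks_nonaff) < 2) return(empty)
  p <- sort(as.integer(peaks_nonaff))
  n_int <- length(p) - 1L
  ts <- function(i) t_offset_s + (i - 1L) / sampling_rate

  aff_kept <- integer(n_int)
  for (k in seq_len(n_int)) {
    lo <- p[k]; hi <- p[k + 1L] - 1L  # half-open [p_k, p_{k+1})
    cand <- aff_candidates[aff_candidates >= lo & aff_candidates <= hi]
    if (length(cand)) {
      aff_kept[k] <- cand[order(-d_aff[cand], cand)][1]
    } else {
      aff_kept[k] <- lo + which.max(d_aff[lo:hi]) - 1L
    }
  }
  trailing <- aff_candidates[aff_candidates > p[length(p)]]
  if (length(trailing)) {
    trailing <- trailing[order(-d_aff[trailing], trailing)][1]
    aff_kept <- c(aff_kept, trailing)
  }

  last_int_s <- (p[length(p)] - p[length(p) - 1L]) / sampling_rate
  aff_start <- ts(aff_kept)
  aff_end <- c(ts(aff_kept)[-1], ts(aff_kept[length(aff_kept)]) + last_int_s)
  strides <- rbind(
    data.frame(side = "NonAff", start_s = ts(p[-length(p)]),
               end_s = ts(p[-1])),
    data.frame(side = "Aff", start_s = aff_start, end_s = aff_end))
  strides$duration_s <- strides$end_s - strides$start_s
  new_stride_sequence(strides, peaks_nonaff = p, peaks_aff = aff_kept)
}

new_stride_sequence <- function(strides, peaks_nonaff, peaks_aff,
                                accepted = TRUE, reason = NA_character_,
                                segment_id = NA_integer_) {
  n_a <- sum(strides$side == "Aff"); n_n <- sum(strides$side == "NonAff")
  if (abs(n_a - n_n) > 1) {
    stop("stride counts differ by more than one between sides")
  }
  structure(list(strides = strides, peaks_nonaff = peaks_nonaff,
                 peaks_aff = peaks_aff, accepted = accepted, reason = reason,
                 segment_id = segment_id),
            class = "stride_sequence")
}

#' @export
print.stride_sequence <- function(x, ...) {
  if (!x$accepted) {
    cat(sprintf("<stride_sequence> rejected (%s)\n", x$reason))
  } else {
    cat(sprintf("<stride_sequence> %d NonAff / %d Aff strides\n",
                sum(x$strides$side == "NonAff"),
                sum(x$strides$side == "Aff")))
  }
  invisible(x)
}

#' Full stride segmentation of one walking segment
#'
#' Composition of the stage-3 filters: periodicity filter on the non-affected
#' vertical signal, median smoothing and differentiation of both thighs,
#' hill-climb peak detection per side, bilateral verification, individual
#' stride-duration bounds of 0.25-3 s, and rejection of segments retaining
#' fewer than `min_strides` consecutive in-bounds strides on the non-affected
#' side.
#'
#' @param y_nonaff,y_aff Vertical-axis thigh acceleration of the segment for
#'   the non-affected and affected side (equal length).
#' @param sampling_rate Hz.
#' @param t_offset_s Absolute time of the segment's first sample.
#' @param median_kernel Median smoothing kernel in samples (default 5).
#' @param ac_threshold Periodicity acceptance threshold (default 0.3).
#' @param stride_bounds_s Admissible stride duration, default `c(0.25, 3)`.
#' @param min_strides Minimum consecutive in-bounds non-affected strides
#'   (default 5).
#' @param min_separation_s,amp_quantile,amp_frac Passed to
#'   [hill_climb_peaks()].
#' @param segment_id Bookkeeping id attached to the result.
#' @return A `stride_sequence`; when any stage rejects, `accepted` is `FALSE`
#'   and `reason` carries the code (`too_short`, `zero_variance`, `aperiodic`,
#'   `too_few_peaks`, `min_strides`).
#' @export
strides_from_segment <- function(y_nonaff, y_aff, sampling_rate = 50,
                                 t_offset_s = 0, median_kernel = 5,
                                 ac_threshold = 0.3,
                                 stride_bounds_s = c(0.25, 3),
                                 min_strides = 5, min_separation_s = 0.25,
                                 amp_quantile = 0.95, amp_frac = 0.3,
                                 segment_id = NA_integer_) {
  stopifnot(length(y_nonaff) == length(y_aff))
  reject <- function(reason) new_stride_sequence(
    data.frame(side = character(0), start_s = numeric(0), end_s = numeric(0),
               duration_s = numeric(0)),
    integer(0), integer(0), accepted = FALSE, reason = reason,
    segment_id = segment_id)

  ok <- periodicity_filter(y_nonaff, sampling_rate, threshold = ac_threshold)
  if (!isTRUE(ok)) return(reject(attr(ok, "reason")))

  d_n <- smooth_derivative(y_nonaff, sampling_rate, median_kernel)
  d_a <- smooth_derivative(y_aff, sampling_rate, median_kernel)
  pk_n <- hill_climb_peaks(d_n, sampling_rate, min_separation_s,
                           amp_quantile, amp_frac)
  pk_a <- hill_climb_peaks(d_a, sampling_rate, min_separation_s,
                           amp_quantile, amp_frac)
  if (length(pk_n) < 2) return(reject("too_few_peaks"))

  seq0 <- pair_bilateral_strides(pk_n, d_a, sampling_rate,
                                 aff_candidates = pk_a,
                                 t_offset_s = t_offset_s)
  st <- seq0$strides
  inb <- st$duration_s >= stride_bounds_s[1] &
    st$duration_s <= stride_bounds_s[2]

  # the >= min_strides rule is anchored on the non-affected side
  non_rows <- which(st$side == "NonAff")
  run <- rle(inb[non_rows])
  max_run <- if (length(run$lengths)) max(c(0, run$lengths[run$values]))
             else 0
  if (max_run < min_strides) return(reject("min_strides"))

  st <- st[inb, , drop = FALSE]
  row.names(st) <- NULL
  n_a <- sum(st$side == "Aff"); n_n <- sum(st$side == "NonAff")
  # bounds filtering is per stride; re-impose the count constraint by trimming
  # trailing strides from the longer side if the two sides drifted apart
  if (abs(n_a - n_n) > 1) {
    long_side <- if (n_a > n_n) "Aff" else "NonAff"
    drop_n <- abs(n_a - n_n) - 1L
    rows <- which(st$side == long_side)
    st <- st[-utils::tail(rows, drop_n), , drop = FALSE]
    row.names(st) <- NULL
  }
  new_stride_sequence(st, seq0$peaks_nonaff, seq0$peaks_aff,
                      segment_id = segment_id)
}
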