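#' Walking-rule thresholds
#'
#' The walking indicator compares the non-affected thigh's 1-s window features
#' against three thresholds: vertical mean above `theta1`, anteroposterior
#' mean below `theta2`, vertical variance above `theta3`. Defaults are the
#' published values: theta1 = 8 m/s^2, theta2 = 4 m/s^2, theta3 = 0.7 (m/s^2)^2
#' for walkers and 0.25 (m/s^2)^2 for wheelchair users.
#'
#' @param locomotion_type `"walker"` or `"wheelchair"`; selects the default
#'   `theta3`.
#' @param theta1,theta2,theta3 Threshold overrides; all must be positive.
#' @return List of class `walking_thresholds`.
#' @export
walking_thresholds <- function(locomotion_type = c("walker", "wheelchair"),
                               theta1 = 8, theta2 = 4, theta3 = NULL) {
  locomotion_type <- match.arg(locomotion_type)
  if (is.null(theta3)) {
    theta3 <- if (locomotion_type == "wheelchair") 0.25 else 0.7
  }
  if (any(c(theta1, theta2, theta3) <= 0)) stop("thresholds must be positive")
  structure(list(locomotion_type = locomotion_type,
                 theta1 = theta1, theta2 = theta2, theta3 = theta3),
            class = "walking_thresholds")
}

#' @export
print.walking_thresholds <- function(x, ...) {
  cat(sprintf("<walking_thresholds> %s: theta1=%g theta2=%g theta3=%g\n",
              x$locomotion_type, x$theta1, x$theta2, x$theta3))
  invisible(x)
}

#' Per-window walking indicator
#'
#' Flags a 1-s window as walking iff all three strict inequalities hold on the
#' non-affected thigh's features: `mu_y > theta1`, `mu_z < theta2` and
#' `var_y > theta3`.
#'
#' @param features Output of [window_features()] for the non-affected thigh;
#'   features from another placement or role are rejected.
#' @param thresholds A [walking_thresholds()] object.
#' @return Logical vector, one flag per window.
#' @export
walking_indicator <- function(features, thresholds) {
  stopifnot(inherits(thresholds, "walking_thresholds"))
  pl <- attr(features, "placement"); ro <- attr(features, "role")
  if (!identical(pl, "thigh") || !identical(ro, "NonAff")) {
    stop("walking_indicator requires features from the non-affected thigh")
  }
  features$mu_y > thresholds$theta1 &
    features$mu_z < thresholds$theta2 &
    features$var_y > thresholds$theta3
}

#' Merge flagged windows into walking segments
#'
#' Maximal runs of consecutive walking-flagged windows become segments; no gap
#' bridging is applied (short spurious segments are removed downstream by the
#' periodicity and minimum-stride filters). Sample intervals are half-open and
#' 0-based on the aligned grid.
#'
#' @param flags Logical vector from [walking_indicator()].
#' @param window_samples Samples per window (default 50).
#' @param sampling_rate Hz (default 50).
#' @return `data.frame`: `segment_id`, `start_window`, `end_window` (inclusive
#'   window indices), `start_sample`, `end_sample` (half-open), `start_s`,
#'   `end_s`, `duration_s`.
#' @export
windows_to_segments <- function(flags, window_samples = 50,
                                sampling_rate = 50) {
  flags <- as.logical(flags)
  out <- data.frame(segment_id = integer(0), start_window = integer(0),
                    end_window = integer(0), start_sample = integer(0),
                    end_sample = integer(0), start_s = numeric(0),
                    end_s = numeric(0), duration_s = numeric(0))
  if (!length(flags) || !any(flags)) return(out)
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  sw <- starts[keep]; ew <- ends[keep]
  out <- data.frame(
    segment_id = seq_along(keep),
    start_window = sw, end_window = ew,
    start_sample = (sw - 1L) * window_samples,
    end_sample = ew * window_samples,
    start_s = (sw - 1L) * window_samples / sampling_rate,
    end_s = ew * window_samples / sampling_rate,
    duration_s = (ew - sw + 1L) * window_samples / sampling_rate)
  out
}

#' Window-level detection truth table
#'
#' Scores predicted walking flags against annotated activity intervals at the
#' windowing granularity. A window counts as annotated-walking iff more than
#' half of it overlaps a walking-labelled interval; it enters the evaluation
#' iff more than half of it is covered by annotations of any label. Quantities
#' are percentages of evaluated windows; undefined ratios are `NaN`, not zero.
#'
#' @param flags Logical per-window predictions (window i covers
#'   `[(i-1), i) * window_s` seconds on the aligned grid).
#' @param annotations `data.frame` with `start_s`, `end_s`, `label`.
#' @param window_s Window length in seconds.
#' @param walking_labels Labels counted as walking ground truth.
#' @return List of class `truth_table`: `tp`, `tn`, `fp`, `fn` (percent),
#'   `sensitivity`, `specificity` (percent), `n_evaluated`.
#' @export
detection_truth_table <- function(flags, annotations, window_s = 1,
                                  walking_labels = c("walk",
                                                     "physiotherapy_walk")) {
  stopifnot(is.data.frame(annotations),
            all(c("start_s", "end_s", "label") %in% names(annotations)))
  n <- length(flags)
  if (!n) stop("no windows to evaluate")
  w0 <- (seq_len(n) - 1) * window_s
  w1 <- w0 + window_s
  cover <- function(ann) {
    cv <- numeric(n)
    for (i in seq_len(nrow(ann))) {
      cv <- cv + pmax(0, pmin(w1, ann$end_s[i]) - pmax(w0, ann$start_s[i]))
    }
    cv
  }
  annotated <- cover(annotations) > window_s / 2
  if (!any(annotated)) stop("annotations cover no evaluated windows")
  walk_ann <- annotations[annotations$label %in% walking_labels, , drop = FALSE]
  lab <- if (nrow(walk_ann)) cover(walk_ann) > window_s / 2 else logical(n)
  p <- as.logical(flags)[annotated]; y <- lab[annotated]
  m <- length(p)
  tp <- sum(p & y); tn <- sum(!p & !y); fp <- sum(p & !y); fn <- sum(!p & y)
  pct <- function(x) 100 * x / m
  ratio <- function(num, den) if (den == 0) NaN else 100 * num / den
  structure(list(tp = pct(tp), tn = pct(tn), fp = pct(fp), fn = pct(fn),
                 sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 n_evaluated = m),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf(paste0("<truth_table> %d windows | TP %.2f%% TN %.2f%% ",
                     "FP %.2f%% FN %.2f%% | sens %.1f%% spec %.1f%%\n"),
              x$n_evaluated, x$tp, x$tn, x$fp, x$fn,
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Mask out annotated segments (e.g. physiotherapy)
#'
#' Natural walking analysis excludes walking that happened during supervised
#' physiotherapy. A segment is dropped when more than half of it overlaps an
#' interval carrying an excluded label.
#'
#' @param segments Output of [windows_to_segments()].
#' @param annotations `data.frame` with `start_s`, `end_s`, `label` (may be
#'   empty or `NULL`, in which case all segments are kept).
#' @param exclude_labels Labels to mask out.
#' @return The segments data.frame with masked rows removed.
#' @export
apply_exclusions <- function(segments, annotations,
                             exclude_labels = "physiotherapy_walk") {
  if (is.null(annotations) || !nrow(segments) || !length(exclude_labels)) {
    return(segments)
  }
  ex <- annotations[annotations$label %in% exclude_labels, , drop = FALSE]
  if (!nrow(ex)) return(segments)
  keep <- vapply(seq_len(nrow(segments)), function(i) {
    ov <- sum(pmax(0, pmin(segments$end_s[i], ex$end_s) -
                     pmax(segments$start_s[i], ex$start_s)))
    ov <= segments$duration_s[i] / 2
  }, logical(1))
  segments[keep, , drop = FALSE]
}
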