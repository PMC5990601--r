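#' Packaged validation fixtures
#'
#' `detection_table()` returns the per-patient walking-detection truth-table
#' percentages (TP/TN/FP/FN, sensitivity, specificity) of the 11-patient
#' evaluation; `parameter_table()` returns the manual-vs-algorithm movement
#' parameters (stride duration, cadence, stride count; both body sides) in
#' long format with the printed relative-error column retained for
#' cross-checking.
#'
#' @return A `data.frame`.
#' @export
detection_table <- function() {
  utils::read.csv(system.file("extdata", "table2_detection.csv",
                              package = "bilatgait"))
}

#' @rdname detection_table
#' @export
parameter_table <- function() {
  utils::read.csv(system.file("extdata", "table3_parameters.csv",
                              package = "bilatgait"))
}

#' Signed relative error of an algorithm value against a manual reference
#'
#' `(manual - algorithm) / manual * 100`: positive when the algorithm
#' underestimates the reference.
#'
#' @param manual Manual reference value(s), non-zero.
#' @param algorithm Algorithm-derived value(s).
#' @return Signed percentage(s).
#' @export
relative_error <- function(manual, algorithm) {
  if (any(manual == 0)) stop("manual reference must be non-zero")
  (manual - algorithm) / manual * 100
}

select_group <- function(records, group) {
  group <- match.arg(group, c("all", "walker", "wheelchair"))
  out <- if (group == "all") records
         else records[records$locomotion_type == group, , drop = FALSE]
  if (!nrow(out)) stop("empty group: ", group)
  out
}

#' Mean relative error per parameter and side
#'
#' Unweighted mean of the per-patient relative errors for a locomotion group,
#' reported to 2 decimals.
#'
#' @param records Long-format validation records as from [parameter_table()].
#' @param group `"all"`, `"walker"` or `"wheelchair"`.
#' @return `data.frame`: `parameter`, `side`, `mean_rel_error`.
#' @export
aggregate_validation <- function(records = parameter_table(), group = "all") {
  r <- select_group(records, group)
  r$rel_error <- relative_error(r$manual, r$algorithm)
  agg <- stats::aggregate(rel_error ~ parameter + side, data = r, FUN = mean)
  names(agg)[3] <- "mean_rel_error"
  agg$mean_rel_error <- round(agg$mean_rel_error, 2)
  agg[order(agg$parameter, agg$side), ]
}

#' Mean detection sensitivity and specificity per group
#'
#' @param records Records as from [detection_table()].
#' @param group `"all"`, `"walker"` or `"wheelchair"`.
#' @return List: `sensitivity`, `specificity` (unweighted means, percent),
#'   `n`.
#' @export
aggregate_detection <- function(records = detection_table(), group = "all") {
  r <- select_group(records, group)
  list(sensitivity = mean(r$sensitivity_pct),
       specificity = mean(r$specificity_pct), n = nrow(r))
}

#' Absolute difference of the two sides' cohort means
#'
#' Averages one parameter over all patients per body side and reports the
#' absolute difference of the two means. The published figures were computed
#' from column means rounded to 2 decimals, so the means are rounded before
#' differencing by default.
#'
#' @param records Records as from [parameter_table()]; all 11 patients must
#'   be present.
#' @param source `"manual"` or `"algorithm"` column.
#' @param parameter `"stride_duration"`, `"cadence"` or `"stride_count"`.
#' @param emulate_rounding Round side means to 2 decimals before differencing
#'   (default `TRUE`).
#' @return Absolute side gap in the parameter's units.
#' @export
side_gap <- function(records = parameter_table(),
                     source = c("manual", "algorithm"),
                     parameter = c("stride_duration", "cadence",
                                   "stride_count"),
                     emulate_rounding = TRUE) {
  source <- match.arg(source); parameter <- match.arg(parameter)
  r <- records[records$parameter == parameter, , drop = FALSE]
  if (length(unique(r$patient_id)) != 11) {
    stop("side_gap needs all 11 patients")
  }
  m <- vapply(c("Aff", "NonAff"), function(sd)
    mean(r[[source]][r$side == sd]), numeric(1))
  if (emulate_rounding) m <- round(m, 2)
  abs(m["NonAff"] - m["Aff"])[[1]]
}
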