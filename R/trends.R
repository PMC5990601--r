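#' Linear recovery trend of a daily parameter series
#'
#' Ordinary least squares `y = alpha + beta * t` with `t` in days since study
#' begin (day 1 = first recording day). Days without walking data are omitted,
#' not zero-filled. For a zero-variance response R^2 is defined as 0.
#'
#' @param t Day indices.
#' @param value Parameter values (same length; NAs dropped pairwise).
#' @param parameter,side Optional labels carried into the result.
#' @return Object of class `trend_model`: `alpha`, `beta`, `r_squared`,
#'   `n_days`, plus labels.
#' @export
fit_linear_trend <- function(t, value, parameter = NA_character_,
                             side = NA_character_) {
  keep <- is.finite(t) & is.finite(value)
  t <- t[keep]; value <- value[keep]
  if (length(t) < 2) stop("need at least 2 days with defined values")
  if (length(unique(t)) < 2) stop("day indices must not be identical")
  fit <- stats::lm(value ~ t)
  ss_tot <- sum((value - mean(value))^2)
  r2 <- if (ss_tot == 0) 0 else
    max(0, min(1, 1 - sum(stats::residuals(fit)^2) / ss_tot))
  structure(list(parameter = parameter, side = side,
                 alpha = unname(stats::coef(fit)[1]),
                 beta = unname(stats::coef(fit)[2]),
                 r_squared = r2, n_days = length(t)),
            class = "trend_model")
}

#' @export
print.trend_model <- function(x, ...) {
  cat(sprintf("<trend_model> %s %s: alpha=%.4g beta=%.4g/day R2=%.3f (n=%d)\n",
              x$parameter, x$side, x$alpha, x$beta, x$r_squared, x$n_days))
  invisible(x)
}

#' Convergence point of the two side trends
#'
#' Solves `alpha_NonAff + beta_NonAff * t = alpha_Aff + beta_Aff * t` for the
#' day at which the affected and non-affected trends intersect. Equal slopes
#' never intersect (classification `parallel`); intersections outside
#' `[1, t_max]` are `capped` and no numeric convergence day is emitted. A
#' convergence day inside the range - even before the last observed day - is
#' reported as `converging` (convergence already achieved).
#'
#' @param model_aff,model_nonaff [fit_linear_trend()] results for the same
#'   parameter.
#' @param t_max Cut-off in days, default 3650 (10 years).
#' @return Object of class `convergence_point`: `t_cp` (days, `NA` when
#'   parallel/capped), `t_raw` (uncapped intersection), `classification`,
#'   `t_max`.
#' @export
convergence_point <- function(model_aff, model_nonaff, t_max = 3650) {
  if (!is.na(model_aff$parameter) && !is.na(model_nonaff$parameter) &&
      !identical(model_aff$parameter, model_nonaff$parameter)) {
    stop("models were fitted on different parameters")
  }
  dbeta <- model_nonaff$beta - model_aff$beta
  # slopes fitted from data are never bitwise equal; treat slope differences
  # at floating-point noise level as parallel
  tol <- 1e-9 * max(1, abs(model_aff$beta), abs(model_nonaff$beta))
  if (abs(dbeta) < tol) {
    res <- list(t_cp = NA_real_, t_raw = NA_real_,
                classification = "parallel")
  } else {
    t_raw <- (model_aff$alpha - model_nonaff$alpha) / dbeta
    if (t_raw < 1 || t_raw > t_max) {
      res <- list(t_cp = NA_real_, t_raw = t_raw, classification = "capped")
    } else {
      res <- list(t_cp = t_raw, t_raw = t_raw, classification = "converging")
    }
  }
  structure(c(res, list(parameter = model_aff$parameter, t_max = t_max)),
            class = "convergence_point")
}

#' @export
print.convergence_point <- function(x, ...) {
  cat(sprintf("<convergence_point> %s: %s%s (t_max=%g)\n",
              x$parameter, x$classification,
              if (!is.na(x$t_cp)) sprintf(" at day %.1f", x$t_cp) else "",
              x$t_max))
  invisible(x)
}

#' Classify the relation of the two side series
#'
#' `parallel` iff the Pearson correlation of the paired daily values is
#' positive with p < 0.05; otherwise `converging` iff the absolute side
#' difference `|y_Aff(t) - y_NonAff(t)|` has a negative fitted slope at the
#' last observed day, else `diverging`. Needs at least 3 common days,
#' otherwise `NA`.
#'
#' @param t Common day indices.
#' @param y_aff,y_nonaff Paired daily values.
#' @return `"parallel"`, `"converging"`, `"diverging"`, or `NA`.
#' @export
classify_trend <- function(t, y_aff, y_nonaff) {
  keep <- is.finite(t) & is.finite(y_aff) & is.finite(y_nonaff)
  t <- t[keep]; y_aff <- y_aff[keep]; y_nonaff <- y_nonaff[keep]
  if (length(t) < 3) return(NA_character_)
  r <- NA_real_; p <- NA_real_
  if (stats::sd(y_aff) > 0 && stats::sd(y_nonaff) > 0) {
    ct <- stats::cor.test(y_aff, y_nonaff)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  if (is.finite(r) && r > 0 && is.finite(p) && p < 0.05) return("parallel")
  gap <- abs(y_aff - y_nonaff)
  slope <- unname(stats::coef(stats::lm(gap ~ t))[2])
  if (is.finite(slope) && slope < 0) "converging" else "diverging"
}

#' Growing-window continuous convergence estimates
#'
#' Refits both side trends on the first `k` recording days for
#' `k = 2, ..., K` and records the convergence point of every window, the
#' basis of the continuous convergence box plots.
#'
#' @param t Day indices (sorted internally).
#' @param y_aff,y_nonaff Per-side daily values.
#' @param t_max Cut-off in days.
#' @param parameter Optional label.
#' @return `data.frame`: `window_days` (k), `t_last` (last day in window),
#'   `t_cp`, `classification`.
#' @export
continuous_convergence <- function(t, y_aff, y_nonaff, t_max = 3650,
                                   parameter = NA_character_) {
  keep <- is.finite(t) & is.finite(y_aff) & is.finite(y_nonaff)
  ord <- order(t[keep])
  t <- t[keep][ord]; y_aff <- y_aff[keep][ord]; y_nonaff <- y_nonaff[keep][ord]
  n <- length(t)
  if (n < 2) stop("need at least 2 recording days")
  rows <- lapply(2:n, function(k) {
    i <- seq_len(k)
    ma <- fit_linear_trend(t[i], y_aff[i], parameter, "Aff")
    mn <- fit_linear_trend(t[i], y_nonaff[i], parameter, "NonAff")
    cp <- convergence_point(ma, mn, t_max)
    data.frame(window_days = k, t_last = t[k], t_cp = cp$t_cp,
               classification = cp$classification)
  })
  do.call(rbind, rows)
}

#' Paired side-difference test
#'
#' Two-sided paired t-test of the daily values of the two body sides. With
#' zero within-pair variance the statistic is undefined: identical series
#' give p = 1 (no evidence of a difference); a constant non-zero difference
#' gives `NA`.
#'
#' @param y_aff,y_nonaff Paired daily values (at least 2 complete pairs).
#' @param alpha Significance level for the flag (default 0.05).
#' @return List: `p_value`, `significant`, `n`.
#' @export
side_difference_test <- function(y_aff, y_nonaff, alpha = 0.05) {
  keep <- is.finite(y_aff) & is.finite(y_nonaff)
  y_aff <- y_aff[keep]; y_nonaff <- y_nonaff[keep]
  n <- length(y_aff)
  if (n < 2) stop("need at least 2 paired days")
  d <- y_aff - y_nonaff
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    p <- if (abs(mean(d)) <= 1e-10 * max(1, max(abs(y_aff)))) 1 else NA_real_
  } else {
    p <- tryCatch(stats::t.test(y_aff, y_nonaff, paired = TRUE)$p.value,
                  error = function(e) NA_real_)
  }
  list(p_value = p, significant = is.finite(p) && p < alpha, n = n)
}

#' Per-patient trend report
#'
#' Runs the full stage-4 analysis for each requested parameter of a daily
#' parameter table: per-side trend fits, classification, convergence point,
#' growing-window convergence series and the paired side-difference test.
#'
#' @param daily Output rows of [daily_summary()] across days (columns
#'   `day`, `side` and the parameter columns).
#' @param parameters Parameter columns to analyse.
#' @param t_max Convergence cut-off in days.
#' @return Named list (one entry per parameter) of trend results; class
#'   `trend_report`.
#' @export
trend_report <- function(daily,
                         parameters = c("stride_count_norm", "dur_mean",
                                        "cad_mean", "sway_mean"),
                         t_max = 3650) {
  out <- list()
  for (par in parameters) {
    a <- daily[daily$side == "Aff", c("day", par)]
    nsub <- daily[daily$side == "NonAff", c("day", par)]
    m <- merge(a, nsub, by = "day", suffixes = c("_aff", "_nonaff"))
    ya <- m[[paste0(par, "_aff")]]; yn <- m[[paste0(par, "_nonaff")]]
    ok <- is.finite(ya) & is.finite(yn)
    if (sum(ok) < 2) {
      out[[par]] <- list(parameter = par, available = FALSE)
      next
    }
    t <- m$day[ok]; ya <- ya[ok]; yn <- yn[ok]
    ma <- fit_linear_trend(t, ya, par, "Aff")
    mn <- fit_linear_trend(t, yn, par, "NonAff")
    cp <- convergence_point(ma, mn, t_max)
    out[[par]] <- list(
      parameter = par, available = TRUE,
      model_aff = unclass(ma), model_nonaff = unclass(mn),
      classification = classify_trend(t, ya, yn),
      convergence = unclass(cp),
      continuous = continuous_convergence(t, ya, yn, t_max, par),
      side_test = side_difference_test(ya, yn))
  }
  structure(out, class = "trend_report")
}

#' @export
print.trend_report <- function(x, ...) {
  cat("<trend_report>\n")
  for (par in names(x)) {
    e <- x[[par]]
    if (!isTRUE(e$available)) {
      cat(sprintf("  %s: insufficient data\n", par)); next
    }
    cat(sprintf("  %s: %s; CP %s; beta Aff %.4g, NonAff %.4g\n",
                par, e$classification,
                if (!is.na(e$convergence$t_cp))
                  sprintf("day %.1f", e$convergence$t_cp)
                else e$convergence$classification,
                e$model_aff$beta, e$model_nonaff$beta))
  }
  invisible(x)
}
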