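## rate_analysis: NADH standard-curve calibration, initial-velocity
## estimation by ordinary least squares over the early linear phase, and
## replicate/inhibition summaries.

#' Fit an NADH standard curve
#'
#' Ordinary least squares of absorbance on concentration, with intercept
#' (not forced through the origin unless `through_origin = TRUE`).
#'
#' @param concentrations known NADH concentrations, uM (>= 3 distinct).
#' @param readings matching absorbance readings, AU.
#' @param through_origin force a zero intercept.
#' @return list of class `standard_curve`: `slope` (AU per uM),
#'   `intercept` (AU), `r_squared`.
#' @export
fit_standard_curve <- function(concentrations, readings,
                               through_origin = FALSE) {
  check_flag(through_origin, "through_origin")
  if (length(concentrations) != length(readings)) {
    abort("concentrations and readings must pair up")
  }
  if (length(concentrations) < 3L) abort("need at least 3 standard points")
  if (length(unique(concentrations)) < 2L) {
    abort("concentrations must be distinct")
  }
  if (stats::var(readings) == 0) {
    abort("zero-variance fit: readings are constant")
  }
  fit <- if (through_origin) {
    stats::lm(readings ~ 0 + concentrations)
  } else {
    stats::lm(readings ~ concentrations)
  }
  coefs <- stats::coef(fit)
  slope <- unname(coefs[["concentrations"]])
  intercept <- if (through_origin) 0 else unname(coefs[["(Intercept)"]])
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((readings - mean(readings))^2)
  structure(list(slope = slope, intercept = intercept, r_squared = r2),
            class = "standard_curve")
}

#' Convert absorbance readings to NADH concentration
#'
#' C = (reading - intercept) / slope, elementwise. Negative computed
#' concentrations are retained (with a warning): they are informative about
#' baseline noise and clipping would bias slope fits.
#'
#' @param curve a `standard_curve`.
#' @param readings absorbance values, AU.
#' @return concentrations, uM.
#' @export
to_concentration <- function(curve, readings) {
  conc <- (readings - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    warning(sprintf("%d computed concentration(s) are negative (retained)",
                    sum(conc < 0)))
  }
  conc
}

#' Initial reaction velocity from one time course
#'
#' OLS slope of concentration versus time over the initial window: the first
#' `window_points` readings (default 6, i.e. 0-10 min at a 2-min cadence) or
#' all readings up to `window_time` minutes. The window is an explicit,
#' reported parameter, never a hidden constant.
#'
#' @param time_min times, minutes (will be sorted).
#' @param conc_uM concentrations, uM.
#' @param window_points number of leading points to fit (>= 3).
#' @param window_time alternative: time bound in minutes (overrides
#'   `window_points` when given).
#' @return slope in uM/min.
#' @export
initial_rate <- function(time_min, conc_uM, window_points = 6L,
                         window_time = NULL) {
  ord <- order(time_min)
  t <- time_min[ord]; y <- conc_uM[ord]
  sel <- if (!is.null(window_time)) {
    which(t <= window_time)
  } else {
    seq_len(min(check_count(window_points, "window_points", 3L), length(t)))
  }
  if (length(sel) < 3L) abort("initial-rate window covers fewer than 3 points")
  unname(stats::coef(stats::lm(y[sel] ~ t[sel]))[2])
}

#' Per-replicate initial rates from a time-course table
#'
#' @param tc a `timecourse` tibble. Absorbance readings require a standard
#'   curve: supplying none is a hard error (no silent unit mixing).
#' @param standard_curve a [fit_standard_curve()] result, required when
#'   `reading_kind` is `"absorbance"`.
#' @inheritParams initial_rate
#' @return tibble `condition`, `replicate`, (`dose`,) `slope` (uM/min).
#' @export
replicate_rates <- function(tc, standard_curve = NULL, window_points = 6L,
                            window_time = NULL) {
  kind <- attr(tc, "reading_kind")
  if (identical(kind, "absorbance")) {
    if (is.null(standard_curve)) {
      abort("absorbance readings need a standard curve for unit conversion")
    }
    conc <- to_concentration(standard_curve, tc$reading)
  } else {
    conc <- tc$reading
  }
  keys <- unique(tc[, c("condition", "replicate")])
  slope <- numeric(nrow(keys))
  dose <- rep(NA_real_, nrow(keys))
  for (k in seq_len(nrow(keys))) {
    sel <- tc$condition == keys$condition[k] &
      tc$replicate == keys$replicate[k]
    slope[k] <- initial_rate(tc$time_min[sel], conc[sel],
                             window_points, window_time)
    if ("dose" %in% names(tc)) dose[k] <- tc$dose[sel][1]
  }
  out <- tibble::tibble(condition = keys$condition,
                        replicate = keys$replicate, slope = slope)
  if ("dose" %in% names(tc)) out$dose <- dose
  out
}

#' Summarize replicate rates and inhibition against a control
#'
#' Per condition: mean rate +/- SD (n-1 denominator) over replicates, a
#' two-tailed t test against the control condition, and percent inhibition
#' 100 * (rate_control - rate_condition) / rate_control. When conditions
#' carry a `dose` column, a Spearman correlation of mean rate against dose
#' is reported as a monotonicity diagnostic for concentration-dependent
#' inhibition.
#'
#' @param rates output of [replicate_rates()].
#' @param control name of the control condition.
#' @param welch use Welch's t test.
#' @return list of class `rate_result`: `summary` tibble (condition, n,
#'   mean_rate, sd_rate, percent_inhibition, t_p_value, (dose)),
#'   `control`, `spearman_rho` (NA without doses).
#' @export
summarize_rates <- function(rates, control, welch = FALSE) {
  if (!(control %in% rates$condition)) {
    abort(sprintf("control condition '%s' not present", control))
  }
  conds <- unique(rates$condition)
  ctrl_slopes <- rates$slope[rates$condition == control]
  rows <- lapply(conds, function(cond) {
    s <- rates$slope[rates$condition == cond]
    p <- if (cond == control) {
      NA_real_
    } else if (length(s) >= 2L && length(ctrl_slopes) >= 2L) {
      two_sample_t(ctrl_slopes, s, welch = welch)$p_value
    } else {
      NA_real_
    }
    tibble::tibble(
      condition = cond, n = length(s),
      mean_rate = mean(s),
      sd_rate = if (length(s) > 1L) stats::sd(s) else NA_real_,
      percent_inhibition = 100 * (mean(ctrl_slopes) - mean(s)) /
        mean(ctrl_slopes),
      t_p_value = p,
      dose = if ("dose" %in% names(rates)) {
        rates$dose[rates$condition == cond][1]
      } else {
        NA_real_
      })
  })
  summary <- do.call(rbind, rows)
  rho <- NA_real_
  if ("dose" %in% names(rates) && !anyNA(summary$dose) &&
      length(unique(summary$dose)) > 2L) {
    rho <- suppressWarnings(
      stats::cor(summary$dose, summary$mean_rate, method = "spearman"))
  }
  structure(list(summary = summary, control = control, spearman_rho = rho),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("<rate_result> control = %s\n", x$control))
  print(as.data.frame(x$summary))
  invisible(x)
}
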