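#' Cell Index from raw impedance
#'
#' The unitless Cell Index of an impedance well:
#' `CI = (Z_i - Z_0) / 15`, with `Z_i` the impedance (Ohm) at a time
#' point and `Z_0` the baseline impedance recorded before cell seeding.
#'
#' @param impedance_ohm numeric vector of impedance readings (Ohm).
#' @param z0_ohm baseline impedance (Ohm) of the well.
#' @return numeric Cell Index series.
#' @export
cell_index <- function(impedance_ohm, z0_ohm) {
  if (length(z0_ohm) != 1L || !is.finite(z0_ohm)) {
    stop("missing or invalid baseline impedance z0")
  }
  (impedance_ohm - z0_ohm) / 15
}

match_time <- function(times, t_ref, tol = 1e-6) {
  i <- which(abs(times - t_ref) <= tol)
  if (length(i) == 0L) {
    stop(sprintf("reference time %g min is not on the recording grid", t_ref))
  }
  i[1L]
}

#' Normalize a Cell Index series to a reference time
#'
#' Divides the series by its value at the reference time (the RTCA
#' convention), so `nCI(t_ref) = 1`. A subtraction variant
#' (`nCI = CI - CI(t_ref)`, so `nCI(t_ref) = 0`) is available behind the
#' `operator` switch.
#'
#' @param ci numeric Cell Index series.
#' @param times_min time grid (minutes), strictly increasing.
#' @param t_ref reference time (must lie on the grid), e.g. the moment of
#'   inhibitor pretreatment or substrate stimulation.
#' @param operator `"divide"` (default) or `"subtract"`.
#' @return normalized Cell Index series.
#' @export
normalize_ci <- function(ci, times_min, t_ref,
                         operator = c("divide", "subtract")) {
  operator <- match.arg(operator)
  if (length(ci) != length(times_min)) stop("ci and times_min lengths differ")
  if (any(diff(times_min) <= 0)) stop("times must be strictly increasing")
  i <- match_time(times_min, t_ref)
  if (operator == "divide") {
    if (ci[i] <= 0) {
      stop(sprintf("CI at reference time is not positive (%.4g); flag well",
                   ci[i]))
    }
    ci / ci[i]
  } else {
    ci - ci[i]
  }
}

#' Subtract the matched vehicle condition
#'
#' Pointwise subtraction of the plate's averaged vehicle-only trace from a
#' condition trace, correcting for vehicle-induced, ligand-independent
#' effects. The time grids must match exactly; no silent interpolation.
#'
#' @param nci condition nCI series.
#' @param vehicle_mean averaged vehicle nCI series on the same grid.
#' @param times_min,vehicle_times_min the two time grids.
#' @return corrected series (vehicle-corrected vehicle is all zeros).
#' @export
vehicle_correct <- function(nci, vehicle_mean, times_min = NULL,
                            vehicle_times_min = NULL) {
  if (!is.null(times_min) && !is.null(vehicle_times_min)) {
    if (length(times_min) != length(vehicle_times_min) ||
        any(abs(times_min - vehicle_times_min) > 1e-6)) {
      stop("resampling error: condition and vehicle time grids differ")
    }
  }
  if (length(nci) != length(vehicle_mean)) {
    stop("resampling error: condition and vehicle series lengths differ")
  }
  nci - vehicle_mean
}

trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Net area under the curve after stimulation
#'
#' Trapezoidal integral of the signed (vehicle-corrected) nCI curve over
#' `[t_from, t_from + window_min]`; negative excursions subtract, making
#' the area "net". Window endpoints falling between grid points are
#' obtained by linear interpolation; a window not fully covered by the
#' recording is an error.
#'
#' @param times_min time grid (minutes).
#' @param values corrected nCI series.
#' @param t_from window start (minutes), typically the stimulation time.
#' @param window_min window length (default 120 minutes).
#' @return net AUC in nCI x min.
#' @export
net_auc <- function(times_min, values, t_from, window_min = 120) {
  t_to <- t_from + window_min
  if (t_from < min(times_min) - 1e-9 || t_to > max(times_min) + 1e-9) {
    stop(sprintf(
      "window [%g, %g] min not covered by the recording span [%g, %g]",
      t_from, t_to, min(times_min), max(times_min)))
  }
  inner <- times_min > t_from & times_min < t_to
  xs <- c(t_from, times_min[inner], t_to)
  ys <- c(stats::approx(times_min, values, xout = t_from)$y,
          values[inner],
          stats::approx(times_min, values, xout = t_to)$y)
  trapezoid(xs, ys)
}

#' Fold expression over a control condition
#'
#' Ratio of the mean measurement (e.g. ELISA absorbance) of a condition
#' over the mean of the control — a ratio of means, not a mean of
#' per-replicate ratios.
#'
#' @param condition_values replicate measurements of the condition.
#' @param control_values replicate measurements of the control.
#' @return fold expression.
#' @export
fold_expression <- function(condition_values, control_values) {
  ctrl <- mean(control_values)
  if (!is.finite(ctrl) || ctrl <= 0) {
    stop("control mean must be positive")
  }
  mean(condition_values) / ctrl
}

#' Dunnett many-to-one comparison against a control group
#'
#' One-way ANOVA followed by Dunnett's post hoc test: every group is
#' compared with the control and p-values are adjusted for the joint
#' multivariate-t distribution of the comparisons.
#'
#' @param values numeric observations.
#' @param groups group labels (same length as `values`).
#' @param control label of the control group.
#' @param alpha significance level (default 0.05).
#' @return list with `anova_F`, `anova_p` and `comparisons` (data.frame:
#'   group, estimate, p_adj, significant).
#' @export
dunnett_vs_control <- function(values, groups, control, alpha = 0.05) {
  groups <- as.character(groups)
  if (!control %in% groups) stop("control group not present: ", control)
  if (length(unique(groups)) < 2L) stop("need at least two groups")
  counts <- table(groups)
  if (any(counts < 2L)) stop("every group needs at least 2 observations")
  if (all(tapply(values, groups, stats::var) < .Machine$double.eps)) {
    stop("degenerate variance: all groups are constant")
  }
  d <- data.frame(y = values,
                  g = stats::relevel(factor(groups), ref = control))
  fit <- stats::aov(y ~ g, data = d)
  ft <- summary(fit)[[1]]
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(gl)
  comp <- data.frame(
    group = sub(" - .*$", "", names(sm$test$coefficients)),
    estimate = as.numeric(sm$test$coefficients),
    p_adj = as.numeric(sm$test$pvalues),
    stringsAsFactors = FALSE
  )
  comp$significant <- comp$p_adj < alpha
  list(anova_F = ft[["F value"]][1], anova_p = ft[["Pr(>F)"]][1],
       comparisons = comp)
}

#' Submaximal (EC80) concentration from EC50 and Hill slope
#'
#' For an ascending variable-slope curve, the concentration giving 80% of
#' the maximal response: `EC80 = EC50 * 4^(1/hill)`.
#'
#' @param ec50_M EC50 in molar.
#' @param hill Hill slope (> 0).
#' @return EC80 in molar.
#' @export
ec80 <- function(ec50_M, hill = 1) {
  if (hill <= 0) stop("EC80 requires a positive Hill slope")
  ec50_M * 4^(1 / hill)
}
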