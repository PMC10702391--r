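#' Fit a variable-slope sigmoidal concentration-response curve
#'
#' Four-parameter logistic fit on log10 concentration:
#' `y = bottom + (top - bottom) / (1 + 10^((log10(XC50) - x) * hill))`.
#' For stimulation data an ascending curve (hill > 0) reports pEC50 and
#' Emax (the fitted top); for inhibition data a descending curve
#' (hill < 0 in this parameterization) reports pIC50. The Hill slope is
#' unconstrained in sign but bounded at |hill| <= 5 for stability.
#'
#' Pathology flags replace parameters rather than raising errors:
#' * `not_determined` — the observed per-concentration mean responses
#'   span less than `span_floor_pct` of the reference (no
#'   concentration-dependent signal), the optimizer fails, the fitted
#'   span (top - bottom) is under the same floor, or the fitted potency
#'   lies more than `range_margin_log` log units outside the tested
#'   concentration range (mirrors "N.D." entries in potency tables; the
#'   margin keeps boundary noise from discarding valid fits). The floor
#'   default of 5% sits below the smallest maximal response at which
#'   potencies are still reported in practice.
#' * `bell_shaped` — stimulation data that rise and then fall: the mean
#'   response of the three highest concentrations is below 70% of the
#'   maximum over the lower concentrations and the terminal slope is
#'   significantly negative. Flagged fits report no potency or Emax.
#'
#' @param concentrations_M concentrations in molar (>= 4 distinct).
#' @param responses responses as % of the reference response (the 1 mM
#'   substrate response on wild-type cells = 100%), replicate-level.
#' @param direction `"stimulation"` or `"inhibition"`.
#' @param span_floor_pct minimum span, % of reference (default 5).
#' @param range_margin_log tolerated overshoot of the fitted potency
#'   beyond the tested range, log10 units (default 0.5).
#' @param bottom_floor lower bound on the fitted bottom asymptote
#'   (default 0: vehicle correction pins the true ligand-independent
#'   baseline at zero, so a negative plateau is not physical; pass a
#'   negative value to relax).
#' @return object of class `dose_response_fit`: `p_potency` (pEC50 or
#'   pIC50, -log10 M), `emax_pct`, `hill`, `bottom`, `se` (per-parameter
#'   standard errors), `flags`, `direction`, `data`.
#' @export
fit_concentration_response <- function(concentrations_M, responses,
                                       direction = c("stimulation",
                                                     "inhibition"),
                                       span_floor_pct = 5,
                                       range_margin_log = 0.5,
                                       bottom_floor = 0) {
  direction <- match.arg(direction)
  stopifnot(length(concentrations_M) == length(responses))
  if (any(concentrations_M <= 0)) stop("concentrations must be positive")
  conc_levels <- sort(unique(concentrations_M))
  if (length(conc_levels) < 4L) {
    stop("need at least 4 distinct concentrations")
  }
  flags <- list(converged = FALSE, not_determined = FALSE,
                bell_shaped = FALSE)
  blank <- function() {
    structure(list(p_potency = NA_real_, emax_pct = NA_real_,
                   hill = NA_real_, bottom = NA_real_,
                   se = list(p_potency = NA_real_, emax_pct = NA_real_,
                             hill = NA_real_, bottom = NA_real_),
                   flags = flags, direction = direction,
                   data = data.frame(conc_M = concentrations_M,
                                     response = responses)),
              class = "dose_response_fit")
  }

  if (direction == "stimulation" &&
      is_bell_shaped(concentrations_M, responses)) {
    flags$bell_shaped <- TRUE
    out <- blank(); out$flags <- flags
    return(out)
  }

  x <- log10(concentrations_M)
  y <- responses
  mean_by <- tapply(y, x, mean)
  xs <- as.numeric(names(mean_by))
  # no concentration-dependent signal in the data themselves
  if (diff(range(mean_by)) < span_floor_pct) {
    flags$not_determined <- TRUE
    out <- blank(); out$flags <- flags
    return(out)
  }
  top0 <- max(mean_by); bot0 <- max(min(mean_by), bottom_floor)
  half <- (top0 + bot0) / 2
  loge0 <- xs[which.min(abs(mean_by - half))]
  hill0 <- if (direction == "stimulation") 1 else -1
  resid_fn <- function(p) {
    y - (p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
           (1 + 10^((p[["loge"]] - x) * p[["hill"]])))
  }
  lower <- c(bottom = bottom_floor, top = -50, loge = min(xs) - 3, hill = -5)
  upper <- c(bottom = 200, top = 250, loge = max(xs) + 3, hill = 5)
  # Levenberg-Marquardt from a deterministic ladder of starts; the first
  # usually suffices
  starts <- list(
    c(bottom = bot0, top = top0, loge = loge0, hill = hill0),
    c(bottom = bottom_floor, top = 1.05 * top0 + 1, loge = loge0 + 0.25,
      hill = 1.2 * hill0),
    c(bottom = bottom_floor, top = 0.9 * top0, loge = loge0 - 0.25,
      hill = 0.8 * hill0))
  fit <- NULL
  for (s0 in starts) {
    cand <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(s0, lower), upper), fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(cand) && cand$info %in% 1:4) { fit <- cand; break }
  }
  if (is.null(fit)) {
    flags$not_determined <- TRUE
    out <- blank(); out$flags <- flags
    return(out)
  }
  cf <- fit$par
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) {
                   stats::setNames(rep(NA_real_, 4), names(cf))
                 })
  span <- abs(cf[["top"]] - cf[["bottom"]])
  in_range <- cf[["loge"]] >= min(xs) - range_margin_log &&
    cf[["loge"]] <= max(xs) + range_margin_log
  if (span < span_floor_pct || !in_range) {
    flags$not_determined <- TRUE
    out <- blank(); out$flags <- flags
    return(out)
  }
  flags$converged <- TRUE
  structure(list(
    p_potency = -cf[["loge"]],
    emax_pct = cf[["top"]],
    hill = cf[["hill"]],
    bottom = cf[["bottom"]],
    se = list(p_potency = unname(se["loge"]), emax_pct = unname(se["top"]),
              hill = unname(se["hill"]), bottom = unname(se["bottom"])),
    flags = flags, direction = direction,
    data = data.frame(conc_M = concentrations_M, response = responses)
  ), class = "dose_response_fit")
}

# Rise-then-fall detection for stimulation curves: the three highest
# concentrations lose most of the interior maximum and the terminal slope
# is significantly negative. Needs >= 5 distinct concentrations.
is_bell_shaped <- function(conc_M, responses, drop_frac = 0.7,
                           min_signal_pct = 15, alpha = 0.05) {
  lev <- sort(unique(conc_M))
  if (length(lev) < 5L) return(FALSE)
  means <- tapply(responses, conc_M, mean)[as.character(lev)]
  n_top <- 3L
  interior_max <- max(means[seq_len(length(lev) - n_top)])
  top_mean <- mean(means[(length(lev) - n_top + 1L):length(lev)])
  if (interior_max < min_signal_pct) return(FALSE)
  if (top_mean >= drop_frac * interior_max) return(FALSE)
  term_lev <- lev[(length(lev) - n_top):length(lev)]  # last 4 concentrations
  keep <- conc_M %in% term_lev
  sl <- stats::lm(responses[keep] ~ log10(conc_M[keep]))
  co <- summary(sl)$coefficients
  co[2, "Estimate"] < 0 && co[2, "Pr(>|t|)"] < alpha
}

#' @export
print.dose_response_fit <- function(x, ...) {
  lab <- if (x$direction == "stimulation") "pEC50" else "pIC50"
  if (x$flags$bell_shaped) {
    cat("<dose_response_fit> bell-shaped; no parameters reported\n")
  } else if (x$flags$not_determined) {
    cat("<dose_response_fit> not determined (N.D.)\n")
  } else {
    cat(sprintf("<dose_response_fit> %s = %.2f, Emax = %.0f%%, hill = %.2f\n",
                lab, x$p_potency, x$emax_pct, x$hill))
  }
  invisible(x)
}

#' Summarize per-experiment fits as mean +/- SEM
#'
#' Experiments are the replication unit: each parameter is averaged
#' across the converged per-experiment fits and reported with its
#' standard error of the mean. If any experiment is flagged bell-shaped
#' or not determined, the corresponding flag is propagated and only
#' converged fits enter the summary.
#'
#' @param fits list of `dose_response_fit` objects (one per experiment).
#' @return object of class `potency_summary`: per-parameter `mean`,
#'   `sem`, `n` (converged experiments), `flags`.
#' @export
potency_summary <- function(fits) {
  stopifnot(length(fits) >= 1L)
  ok <- vapply(fits, function(f) isTRUE(f$flags$converged), logical(1))
  flags <- list(
    not_determined = any(vapply(fits, function(f) f$flags$not_determined,
                                logical(1))),
    bell_shaped = any(vapply(fits, function(f) f$flags$bell_shaped,
                             logical(1)))
  )
  param <- function(name) vapply(fits[ok], function(f) f[[name]], numeric(1))
  summ <- function(v) {
    if (length(v) == 0L) return(c(mean = NA_real_, sem = NA_real_))
    c(mean = mean(v),
      sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0)
  }
  structure(list(
    p_potency = summ(param("p_potency")),
    emax_pct = summ(param("emax_pct")),
    hill = summ(param("hill")),
    bottom = summ(param("bottom")),
    n = sum(ok), flags = flags,
    direction = fits[[1]]$direction
  ), class = "potency_summary")
}

#' @export
print.potency_summary <- function(x, ...) {
  lab <- if (x$direction == "stimulation") "pEC50" else "pIC50"
  if (x$n == 0L) {
    cat(sprintf("<potency_summary> no converged fits (%s)\n",
                paste(names(Filter(isTRUE, x$flags)), collapse = ", ")))
  } else {
    cat(sprintf("<potency_summary> %s = %.2f +/- %.2f (n = %d)\n",
                lab, x$p_potency["mean"], x$p_potency["sem"], x$n))
  }
  invisible(x)
}
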