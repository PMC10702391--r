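#' Construct an impedance plate object
#'
#' Holds the raw impedance traces of one experiment together with the
#' well layout and the protocol event times. Every non-vehicle condition
#' must have a matching vehicle well on the plate.
#'
#' @param traces long-format data.frame: `well`, `time_min`,
#'   `impedance_ohm`.
#' @param layout data.frame: `well`, `role` (one of `"vehicle"`,
#'   `"reference"`, `"substrate"`, `"inhibitor"`), `cell_line`,
#'   `compound`, `conc_M` (dose of the varied compound; `NA` for vehicle
#'   and reference wells), `stim_compound`, `stim_conc_M`.
#' @param z0_ohm named numeric vector of baseline impedances per well.
#' @param events list with `t_pretreat_min` and `t_stimulate_min`.
#' @param meta free-form provenance list (e.g. the generator spec).
#' @return object of class `plate`.
#' @export
plate <- function(traces, layout, z0_ohm, events, meta = list()) {
  stopifnot(all(c("well", "time_min", "impedance_ohm") %in% names(traces)))
  stopifnot(all(c("well", "role", "conc_M") %in% names(layout)))
  if (!all(layout$well %in% names(z0_ohm))) {
    stop("every well needs a baseline impedance z0")
  }
  if (!any(layout$role == "vehicle")) {
    stop("plate has no vehicle wells to correct against")
  }
  stopifnot(is.numeric(events$t_pretreat_min),
            is.numeric(events$t_stimulate_min))
  structure(list(traces = traces, layout = layout, z0_ohm = z0_ohm,
                 events = events, meta = meta), class = "plate")
}

#' @export
print.plate <- function(x, ...) {
  cat(sprintf("<plate> %d wells (%s), pretreat %g min, stimulate %g min\n",
              nrow(x$layout),
              paste(sprintf("%s:%d", names(table(x$layout$role)),
                            as.integer(table(x$layout$role))),
                    collapse = " "),
              x$events$t_pretreat_min, x$events$t_stimulate_min))
  invisible(x)
}

#' Read a plate from trace and layout CSV files
#'
#' The trace CSV is long format (`well`, `time_min`, `impedance_ohm`);
#' baseline rows are the `time_min < 0` records (their mean per well is
#' `z0`), or a `z0_ohm` column in the layout.
#'
#' @param traces_csv,layout_csv file paths.
#' @param t_pretreat_min,t_stimulate_min protocol event times (minutes).
#' @return a [plate].
#' @export
read_plate_csv <- function(traces_csv, layout_csv, t_pretreat_min,
                           t_stimulate_min) {
  traces <- utils::read.csv(traces_csv, stringsAsFactors = FALSE)
  layout <- utils::read.csv(layout_csv, stringsAsFactors = FALSE)
  if (!is.null(layout$z0_ohm)) {
    z0 <- stats::setNames(layout$z0_ohm, layout$well)
  } else {
    base <- traces[traces$time_min < 0, ]
    if (nrow(base) == 0L) stop("no baseline: need time_min < 0 rows or a z0_ohm column")
    z0 <- tapply(base$impedance_ohm, base$well, mean)
    traces <- traces[traces$time_min >= 0, ]
  }
  plate(traces, layout, z0,
        list(t_pretreat_min = t_pretreat_min,
             t_stimulate_min = t_stimulate_min))
}

plate_nci <- function(p, mode) {
  t_ref <- if (mode == "inhibition") p$events$t_pretreat_min else
    p$events$t_stimulate_min
  wells <- split(p$traces, p$traces$well)
  times <- sort(unique(p$traces$time_min))
  nci <- sapply(p$layout$well, function(w) {
    tr <- wells[[w]]
    tr <- tr[order(tr$time_min), ]
    if (length(tr$time_min) != length(times) ||
        any(abs(tr$time_min - times) > 1e-6)) {
      stop("resampling error: well ", w, " is not on the common time grid")
    }
    ci <- cell_index(tr$impedance_ohm, p$z0_ohm[[w]])
    normalize_ci(ci, tr$time_min, t_ref)
  })
  list(times = times, nci = nci)   # nci: time x well matrix
}

#' Quantify one impedance experiment
#'
#' Full forward pass for a single plate: Cell Index, normalization (to
#' the stimulation time for substrate plates, to the pretreatment time
#' for inhibitor plates), vehicle correction, net AUC over the 120 min
#' post-stimulation window, normalization of AUCs to the plate's
#' reference wells (100%), and a variable-slope concentration-response
#' fit.
#'
#' @param p a [plate].
#' @param mode `"stimulation"` (substrate series) or `"inhibition"`
#'   (inhibitor pretreatment series).
#' @param window_min AUC window (default 120 minutes).
#' @return list with `fit` (a `dose_response_fit`), `responses`
#'   (per-well conc/AUC/% response), `reference_auc`.
#' @export
quantify_experiment <- function(p, mode = c("stimulation", "inhibition"),
                                window_min = 120) {
  mode <- match.arg(mode)
  nc <- plate_nci(p, mode)
  veh_wells <- p$layout$well[p$layout$role == "vehicle"]
  veh_mean <- rowMeans(nc$nci[, veh_wells, drop = FALSE])
  corrected <- nc$nci - veh_mean
  auc <- apply(corrected, 2, function(v) {
    net_auc(nc$times, v, p$events$t_stimulate_min, window_min)
  })
  ref_wells <- p$layout$well[p$layout$role == "reference"]
  if (length(ref_wells) == 0L) stop("plate has no reference wells")
  ref_auc <- mean(auc[ref_wells])
  if (abs(ref_auc) < .Machine$double.eps) stop("reference response is zero")
  dose_role <- if (mode == "stimulation") "substrate" else "inhibitor"
  dose <- p$layout[p$layout$role == dose_role, , drop = FALSE]
  if (nrow(dose) == 0L) stop("plate has no ", dose_role, " wells")
  responses <- data.frame(
    well = dose$well, conc_M = dose$conc_M,
    net_auc = auc[dose$well],
    response_pct = 100 * auc[dose$well] / ref_auc,
    stringsAsFactors = FALSE)
  fit <- fit_concentration_response(responses$conc_M,
                                    responses$response_pct,
                                    direction = mode)
  list(fit = fit, responses = responses, reference_auc = ref_auc)
}

#' Quantify a multi-experiment study
#'
#' Runs [quantify_experiment()] on each plate (one per independent
#' experiment) and summarizes the per-experiment fits as mean +/- SEM.
#'
#' @param plates list of [plate] objects.
#' @inheritParams quantify_experiment
#' @return list with `summary` (a `potency_summary`), `fits`,
#'   `experiments`.
#' @export
quantify_study <- function(plates, mode = c("stimulation", "inhibition"),
                           window_min = 120) {
  mode <- match.arg(mode)
  runs <- lapply(plates, quantify_experiment, mode = mode,
                 window_min = window_min)
  fits <- lapply(runs, `[[`, "fit")
  list(summary = potency_summary(fits), fits = fits, experiments = runs)
}
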