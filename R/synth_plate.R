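#' Specification for the synthetic impedance-plate generator
#'
#' Declares the planted concentration-response truth for a set of
#' impedance experiments. Responses are expressed in percent of the
#' reference response (the 1 mM substrate response on wild-type cells =
#' 100%); the generator builds well traces whose net AUC after the full
#' Cell Index / normalization / vehicle-correction pipeline equals the
#' planted response, so the forward pass is the generator's statistical
#' inverse.
#'
#' @param true_p_potency planted pEC50 (stimulation) or pIC50
#'   (inhibition), -log10 molar.
#' @param true_emax_pct planted maximal response, % of reference.
#' @param true_hill planted Hill slope magnitude (sign is set by `mode`).
#' @param bottom planted lower asymptote, % of reference.
#' @param mode `"stimulation"` (substrate series) or `"inhibition"`
#'   (inhibitor pretreatment before a fixed submaximal stimulation).
#' @param shape `"sigmoid"`, `"flat"` (no concentration dependence) or
#'   `"bell"` (rise-then-fall; stimulation only).
#' @param concentrations_M tested concentrations (>= 4 distinct for
#'   sigmoid; defaults: half-log 10 uM-1 mM for substrates, 1 nM-10 uM
#'   for inhibitors).
#' @param duplicates wells per condition per experiment (default 2).
#' @param n_experiments independent experiments (default 3).
#' @param noise_sd_pct amplitude noise as a percent coefficient of
#'   variation of each well's response, plus a small additive floor
#'   (default 5).
#' @param vehicle_drift list(amp, tau_min): vehicle-induced nCI drift
#'   added to every well and removed again by vehicle correction.
#' @param bell_c_M,bell_m high-concentration decay parameters for
#'   `shape = "bell"`.
#' @param seed integer seed.
#' @return validated spec of class `plate_gen_spec`.
#' @export
plate_gen_spec <- function(true_p_potency = 3.5, true_emax_pct = 100,
                           true_hill = 1, bottom = 0,
                           mode = c("stimulation", "inhibition"),
                           shape = c("sigmoid", "flat", "bell"),
                           concentrations_M = NULL, duplicates = 2L,
                           n_experiments = 3L, noise_sd_pct = 5,
                           vehicle_drift = list(amp = 0.15, tau_min = 60),
                           bell_c_M = 10^-4.6, bell_m = 2, seed = 1L) {
  mode <- match.arg(mode)
  shape <- match.arg(shape)
  if (is.null(concentrations_M)) {
    concentrations_M <- if (mode == "inhibition") {
      10^seq(-9, -5, by = 0.5)
    } else if (shape == "bell") {
      10^seq(-6, -3, by = 0.5)
    } else {
      10^seq(-5, -3, by = 0.5)
    }
  }
  if (any(concentrations_M <= 0)) stop("invalid spec: concentrations must be positive")
  if (shape == "sigmoid" && length(unique(concentrations_M)) < 4L) {
    stop("invalid spec: sigmoid shape needs >= 4 distinct concentrations")
  }
  if (shape == "bell" && mode == "inhibition") {
    stop("invalid spec: bell shape applies to stimulation data")
  }
  if (noise_sd_pct < 0) stop("invalid spec: noise_sd_pct must be >= 0")
  structure(list(true_p_potency = true_p_potency,
                 true_emax_pct = true_emax_pct, true_hill = true_hill,
                 bottom = bottom, mode = mode, shape = shape,
                 concentrations_M = sort(concentrations_M),
                 duplicates = as.integer(duplicates),
                 n_experiments = as.integer(n_experiments),
                 noise_sd_pct = noise_sd_pct,
                 vehicle_drift = vehicle_drift,
                 bell_c_M = bell_c_M, bell_m = bell_m,
                 seed = as.integer(seed)),
            class = "plate_gen_spec")
}

#' Planted response at a concentration
#'
#' The generator's ground-truth response (% of reference) at a given
#' concentration, under the spec's shape and mode.
#'
#' @param spec a `plate_gen_spec`.
#' @param conc_M concentration(s), molar.
#' @return response in % of reference.
#' @export
planted_response <- function(spec, conc_M) {
  if (spec$shape == "flat") return(rep(0, length(conc_M)))
  loge <- -spec$true_p_potency
  hill <- if (spec$mode == "inhibition") -abs(spec$true_hill) else
    abs(spec$true_hill)
  top <- if (spec$mode == "inhibition") 100 else spec$true_emax_pct
  y <- spec$bottom + (top - spec$bottom) /
    (1 + 10^((loge - log10(conc_M)) * hill))
  if (spec$shape == "bell") {
    y <- y / (1 + (conc_M / spec$bell_c_M)^spec$bell_m)
  }
  y
}

#' Hill slope implied by a reference-normalized potency table
#'
#' Potency tables normalized to the response of a fixed reference
#' concentration (100%) sometimes print fitted maxima above 100%. For
#' such rows the ascending variable-slope curve is only self-consistent
#' for one Hill slope: the one at which the curve passes through 100% at
#' the reference concentration. This helper solves for it; rows with
#' `emax_pct <= 100` carry no constraint and return `default`.
#'
#' @param emax_pct fitted maximal response, % of reference.
#' @param p_potency pEC50, -log10 molar.
#' @param ref_conc_M reference concentration (default 1e-3, i.e. 1 mM).
#' @param default slope returned when no constraint applies.
#' @return Hill slope.
#' @export
hill_for_reference <- function(emax_pct, p_potency, ref_conc_M = 1e-3,
                               default = 1) {
  if (emax_pct <= 100) return(default)
  num <- log10(emax_pct / 100 - 1)
  den <- -p_potency - log10(ref_conc_M)
  if (abs(den) < 1e-9) return(default)
  h <- num / den
  if (!is.finite(h) || h <= 0) default else h
}

# Shared assay timeline (minutes): growth, pretreatment at 120,
# stimulation at 180, recording until 312 so the 120 min AUC window is
# fully covered.
plate_times <- function() c(seq(0, 110, by = 10), seq(120, 312, by = 2))

#' Generate synthetic impedance plates
#'
#' Emits one [plate] per experiment. Impedance traces are built by
#' inverting the Cell Index formula around the planted normalized-CI
#' curves, so running [quantify_experiment()] on a noiseless spec
#' recovers the planted potency to numerical precision. Each plate holds
#' vehicle wells, reference wells (planted 100% response) and the dose
#' series (`substrate` or `inhibitor` role per `mode`). Planted per-well
#' truth is stored in `plate$meta`.
#'
#' @param spec a `plate_gen_spec`.
#' @return list of [plate] objects (length `n_experiments`).
#' @export
gen_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_gen_spec"))
  times <- plate_times()
  t_pre <- 120; t_stim <- 180; window <- 120
  t_ref <- if (spec$mode == "inhibition") t_pre else t_stim
  growth <- function(t) 1 + 1.2 * (1 - exp(-t / 180))
  g_norm <- growth(times) / growth(t_ref)
  drift <- ifelse(times > t_stim,
                  spec$vehicle_drift$amp *
                    (1 - exp(-(times - t_stim) / spec$vehicle_drift$tau_min)),
                  0)
  ramp <- pmin(pmax((times - t_stim) / window, 0), 1)
  cv <- spec$noise_sd_pct / 100
  addl_floor <- if (spec$noise_sd_pct > 0) 0.005 else 0
  trace_sd <- if (spec$noise_sd_pct > 0) 0.002 else 0
  dose_role <- if (spec$mode == "inhibition") "inhibitor" else "substrate"

  with_local_seed(spec$seed, {
    lapply(seq_len(spec$n_experiments), function(exp_i) {
      layout <- rbind(
        data.frame(role = "vehicle", conc_M = NA_real_,
                   stringsAsFactors = FALSE)[rep(1, spec$duplicates), ],
        data.frame(role = "reference", conc_M = NA_real_,
                   stringsAsFactors = FALSE)[rep(1, spec$duplicates), ],
        expand.grid(role = dose_role, conc_M = spec$concentrations_M,
                    dup = seq_len(spec$duplicates),
                    stringsAsFactors = FALSE)[, c("role", "conc_M")]
      )
      layout$well <- sprintf("W%02d", seq_len(nrow(layout)))
      layout$cell_line <- "synthetic"
      layout$compound <- ifelse(layout$role == dose_role, "test-compound", "vehicle")
      layout$stim_compound <- if (spec$mode == "inhibition") "substrate-EC80" else
        ifelse(layout$role == "vehicle", "vehicle", "substrate")
      layout$stim_conc_M <- ifelse(layout$role == "vehicle", NA_real_, 1e-3)
      planted_A <- ifelse(
        layout$role == "vehicle", 0,
        ifelse(layout$role == "reference", 1,
               planted_response(spec, layout$conc_M) / 100))
      traces <- vector("list", nrow(layout))
      z0 <- stats::setNames(stats::runif(nrow(layout), 10, 20), layout$well)
      nci_planted <- matrix(0, length(times), nrow(layout),
                            dimnames = list(NULL, layout$well))
      for (w in seq_len(nrow(layout))) {
        a <- planted_A[w] * (1 + stats::rnorm(1, 0, cv)) +
          stats::rnorm(1, 0, addl_floor)
        eps <- stats::rnorm(length(times), 0, trace_sd)
        eps[times == t_ref] <- 0
        nci <- g_norm + drift + a * ramp + eps
        nci_planted[, w] <- nci
        c0 <- stats::runif(1, 1.8, 2.2)   # CI at the reference time
        z <- 15 * nci * c0 + z0[[w]]
        traces[[w]] <- data.frame(well = layout$well[w], time_min = times,
                                  impedance_ohm = z,
                                  stringsAsFactors = FALSE)
      }
      plate(do.call(rbind, traces),
            layout[, c("well", "role", "cell_line", "compound", "conc_M",
                       "stim_compound", "stim_conc_M")],
            z0,
            events = list(t_pretreat_min = t_pre, t_stimulate_min = t_stim),
            meta = list(spec = spec, experiment = exp_i,
                        planted_response_pct = 100 * planted_A,
                        nci_planted = nci_planted))
    })
  })
}

#' Generate a synthetic somatic variant table
#'
#' Creates a GDC-style variant table with a known number of unique
#' missense changes and known per-position recurrence, for exercising
#' the variant-parsing and frequency operations with planted truth.
#'
#' @param n_patients number of patients in the cohort.
#' @param positions_pool residue positions; one unique missense change is
#'   planted per position.
#' @param recurrence expected number of extra (recurrent) observations
#'   per change (Poisson mean).
#' @param gene gene symbol (default `"SLC1A3"`).
#' @param seed integer seed.
#' @return list with `table` (data.frame: gene, protein_change,
#'   cancer_type, patient_id) and `truth` (n_unique, n_mutations,
#'   per-change counts).
#' @export
gen_variant_table <- function(n_patients, positions_pool, recurrence = 0.3,
                              gene = "SLC1A3", seed = 1L) {
  if (length(positions_pool) == 0L) stop("positions_pool must be non-empty")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  cancers <- c("UCEC", "LUAD", "SKCM", "COAD", "GBM")
  with_local_seed(seed, {
    ref <- sample(aa, length(positions_pool), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(aa, r), 1L), "")
    changes <- paste0(ref, positions_pool, alt)
    counts <- 1L + stats::rpois(length(changes), recurrence)
    rows <- rep(seq_along(changes), counts)
    tab <- data.frame(
      gene = gene,
      protein_change = changes[rows],
      cancer_type = sample(cancers, length(rows), replace = TRUE),
      patient_id = sprintf("P%04d", sample.int(n_patients, length(rows),
                                               replace = TRUE)),
      stringsAsFactors = FALSE)
    tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
    rownames(tab) <- NULL
    list(table = tab,
         truth = list(n_unique = length(changes),
                      n_mutations = nrow(tab),
                      counts = stats::setNames(counts, changes)))
  })
}
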