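#' Run configuration
#'
#' Aggregates the pipeline's tunable thresholds with their defaults: the
#' ligand-proximity cutoff (5 Angstrom), the trajectory instability
#' exclusion threshold (10 Angstrom), the post-stimulation AUC window
#' (120 min), the significance level (0.05) and the number of
#' representative frames (5). The configuration is serialized alongside
#' every workflow output for provenance.
#'
#' @param cutoff_A ligand-proximity cutoff, Angstrom.
#' @param rmsd_exclude_A instability exclusion threshold, Angstrom.
#' @param auc_window_min net-AUC window, minutes.
#' @param alpha significance level.
#' @param k_frames representative frames to select.
#' @param normalization nCI operator, `"divide"` or `"subtract"`.
#' @param seed integer seed for stochastic steps.
#' @return list of class `run_config`.
#' @export
run_config <- function(cutoff_A = 5, rmsd_exclude_A = 10,
                       auc_window_min = 120, alpha = 0.05, k_frames = 5L,
                       normalization = c("divide", "subtract"), seed = 1L) {
  normalization <- match.arg(normalization)
  vals <- c(cutoff_A, rmsd_exclude_A, auc_window_min, alpha, k_frames)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all thresholds must be positive")
  }
  structure(list(cutoff_A = cutoff_A, rmsd_exclude_A = rmsd_exclude_A,
                 auc_window_min = auc_window_min, alpha = alpha,
                 k_frames = as.integer(k_frames),
                 normalization = normalization, seed = as.integer(seed)),
            class = "run_config")
}

write_config <- function(config, dir) {
  jsonlite::write_json(unclass(config), file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Gate-metric workflow: analyze, pool, select representative frames
#'
#' Runs [analyze_trajectories()] over a replicate set, pools the chain-A
#' HP2-opening series of the non-excluded systems, builds the
#' HP2-opening versus ligand-RMSD sampling-density landscape, and
#' selects representative frames at the most frequent opening. When
#' `outdir` is given, metrics, exclusion manifest, density grid,
#' selection and configuration are written as CSV/JSON (and the selected
#' frames as PDB).
#'
#' @param trajs list of [trajectory] objects (one system).
#' @param config a [run_config].
#' @param outdir optional output directory.
#' @param selection_chain chain pooled for frame selection (default
#'   `"A"`).
#' @return list with `analysis`, `density`, `selection`.
#' @export
run_gate_workflow <- function(trajs, config = run_config(), outdir = NULL,
                              selection_chain = "A") {
  analysis <- analyze_trajectories(trajs,
                                   exclude_threshold_A = config$rmsd_exclude_A)
  gate <- pool_metric(analysis, "hp2_opening")
  lig <- pool_metric(analysis, "ligand_rmsd")
  dens <- sampling_density(gate$value, lig$value)
  gate_a <- pool_metric(analysis, "hp2_opening", chains = selection_chain)
  sel <- select_representative_frames(gate_a, k = config$k_frames,
                                      seed = config$seed)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    utils::write.csv(analysis$metrics, file.path(outdir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(analysis$exclusions,
                     file.path(outdir, "exclusions.csv"), row.names = FALSE)
    utils::write.csv(analysis$rmsf, file.path(outdir, "rmsf.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(dens$density),
                     file.path(outdir, "density_grid.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(system = trajs[[1]]$system_label,
           mean_A = sel$mean_A, sd_A = sel$sd_A, mode_A = sel$mode_A,
           window_A = sel$window_A, k = sel$k,
           frames = sel$frames),
      file.path(outdir, "frame_selection.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    export_frames(sel, trajs, file.path(outdir, "frames"),
                  chain = selection_chain)
    write_config(config, outdir)
  }
  list(analysis = analysis, density = dens, selection = sel)
}

#' Plate-quantification workflow
#'
#' Quantifies a multi-experiment impedance study and, when `outdir` is
#' given, writes a potency table (mean +/- SEM with flags) plus per-well
#' responses and the configuration.
#'
#' @param plates list of [plate] objects.
#' @param mode `"stimulation"` or `"inhibition"`.
#' @param config a [run_config].
#' @param outdir optional output directory.
#' @param label condition label used in the output table.
#' @return the [quantify_study()] result, with `table` appended.
#' @export
run_plate_workflow <- function(plates, mode = "stimulation",
                               config = run_config(), outdir = NULL,
                               label = "condition") {
  res <- quantify_study(plates, mode = mode,
                        window_min = config$auc_window_min)
  s <- res$summary
  res$table <- data.frame(
    condition = label,
    measure = if (mode == "stimulation") "pEC50" else "pIC50",
    value = unname(s$p_potency["mean"]), sem = unname(s$p_potency["sem"]),
    emax_pct = unname(s$emax_pct["mean"]),
    emax_sem = unname(s$emax_pct["sem"]),
    hill = unname(s$hill["mean"]), n = s$n,
    flag = if (s$flags$bell_shaped) "bell_shaped" else
      if (s$flags$not_determined) "not_determined" else "ok",
    stringsAsFactors = FALSE)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    utils::write.csv(res$table, file.path(outdir, "potency_table.csv"),
                     row.names = FALSE)
    resp <- do.call(rbind, lapply(seq_along(res$experiments), function(i) {
      r <- res$experiments[[i]]$responses
      r$experiment <- i
      r
    }))
    utils::write.csv(resp, file.path(outdir, "responses.csv"),
                     row.names = FALSE)
    write_config(config, outdir)
  }
  res
}

#' Assemble a human-readable summary report from workflow outputs
#'
#' Collects the artifacts written by [run_gate_workflow()] and
#' [run_plate_workflow()] (and the variant-classification CSVs if
#' present) from a results directory into one markdown document.
#' Missing stages are marked as gaps rather than failing the report;
#' a directory with no recognized artifacts is an error.
#'
#' @param results_dir directory holding stage outputs (searched
#'   recursively).
#' @param out output file (default `report.md` inside `results_dir`).
#' @return path of the written report, invisibly.
#' @export
report <- function(results_dir, out = file.path(results_dir, "report.md")) {
  if (!dir.exists(results_dir)) stop("results directory not found: ", results_dir)
  find1 <- function(name) {
    hits <- list.files(results_dir, pattern = paste0("^", name, "$"),
                       recursive = TRUE, full.names = TRUE)
    if (length(hits) >= 1L) hits[1L] else NULL
  }
  lines <- c("# Pipeline summary report", "")
  found_any <- FALSE

  sel <- find1("frame_selection.json")
  if (!is.null(sel)) {
    found_any <- TRUE
    s <- jsonlite::read_json(sel, simplifyVector = TRUE)
    lines <- c(lines, "## Representative HP2-opening frames", "",
               sprintf("- System: %s", s$system),
               sprintf("- Selected %d frames at %.2f +/- %.2f A (modal bin %.2f A)",
                       s$k, s$mean_A, s$sd_A, s$mode_A), "")
  } else {
    lines <- c(lines, "## Representative HP2-opening frames", "",
               "_No frame selection found._", "")
  }

  excl <- find1("exclusions.csv")
  if (!is.null(excl)) {
    found_any <- TRUE
    e <- utils::read.csv(excl, stringsAsFactors = FALSE)
    flagged <- e[e$excluded, , drop = FALSE]
    lines <- c(lines, "## Excluded (replicate, chain) systems", "")
    if (nrow(flagged) == 0L) {
      lines <- c(lines, "None excluded.", "")
    } else {
      lines <- c(lines,
                 sprintf("- replicate %d chain %s (max protein RMSD %.1f A)",
                         flagged$replicate, flagged$chain,
                         flagged$max_protein_rmsd_A), "")
    }
  } else {
    lines <- c(lines, "## Excluded (replicate, chain) systems", "",
               "_No exclusion manifest found._", "")
  }

  pot <- find1("potency_table.csv")
  if (!is.null(pot)) {
    found_any <- TRUE
    p <- utils::read.csv(pot, stringsAsFactors = FALSE)
    lines <- c(lines, "## Potency table", "",
               paste(names(p), collapse = " | "),
               paste(rep("---", ncol(p)), collapse = " | "),
               apply(p, 1, function(r) paste(r, collapse = " | ")), "")
  } else {
    lines <- c(lines, "## Potency table", "", "_No potency table found._", "")
  }

  prox <- find1("proximity_sets.csv")
  if (!is.null(prox)) {
    found_any <- TRUE
    q <- utils::read.csv(prox, stringsAsFactors = FALSE)
    lines <- c(lines, "## Variant proximity classification", "",
               paste(names(q), collapse = " | "),
               paste(rep("---", ncol(q)), collapse = " | "),
               apply(q, 1, function(r) paste(r, collapse = " | ")), "")
  }

  if (!found_any) {
    stop("no recognized stage outputs under ", results_dir)
  }
  writeLines(lines, out)
  invisible(out)
}

#' Recover a planted potency with the full pipeline
#'
#' Convenience wrapper tying generator and quantification together:
#' generates plates from a [plate_gen_spec()] and reports the pipeline's
#' recovered potency summary. This is the package's parameter-recovery
#' harness.
#'
#' @param spec a `plate_gen_spec`.
#' @return the [quantify_study()] result.
#' @export
recover_potency <- function(spec) {
  quantify_study(gen_plate(spec), mode = spec$mode)
}
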