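metric_series <- function(values, traj, chain, metric_name) {
  data.frame(
    system = traj$system_label,
    replicate = traj$replicate_id,
    chain = chain,
    metric = metric_name,
    frame = seq_along(values),
    time_ps = (seq_along(values) - 1) * traj$dt_ps,
    value = as.numeric(values),
    stringsAsFactors = FALSE
  )
}

protein_ca_idx <- function(traj, chain) {
  idx <- atom_indices(traj$topology, chain = chain, elety = "CA", het = FALSE)
  if (length(idx) == 0L) {
    stop("no protein C-alpha atoms in chain ", chain)
  }
  idx
}

#' Superpose every trajectory frame onto the first frame
#'
#' Removes global rotation and translation by least-squares fitting each
#' frame onto frame 1. The fit subset defaults to the protein C-alpha
#' atoms of the chain under analysis (each chain is analyzed
#' independently downstream); the resulting rigid transform is applied to
#' all atoms of the frame so that ions and ligands follow their chain.
#'
#' @param traj a [trajectory].
#' @param chain chain whose C-alpha atoms define the fit subset.
#' @param fit_idx optional explicit fit subset (atom indices), overriding
#'   `chain`.
#' @return a fitted [trajectory].
#' @export
fit_trajectory <- function(traj, chain = "A", fit_idx = NULL) {
  if (is.null(fit_idx)) fit_idx <- protein_ca_idx(traj, chain)
  ref <- traj$frames[1L, , , drop = TRUE]
  out <- traj$frames
  for (i in seq_len(n_frames(traj))) {
    sp <- superpose(traj$frames[i, , , drop = TRUE], ref, fit_idx)
    out[i, , ] <- sp$fitted
  }
  traj$frames <- out
  traj$fitted <- TRUE
  traj
}

#' Per-frame protein C-alpha RMSD versus frame 1
#'
#' The trajectory is expected to be superposed first
#' ([fit_trajectory()]); the RMSD of frame 1 against itself is exactly 0.
#'
#' @param traj a fitted [trajectory].
#' @param chain chain to measure.
#' @return metric-series data.frame (system, replicate, chain, metric,
#'   frame, time_ps, value).
#' @export
protein_rmsd <- function(traj, chain = "A") {
  idx <- protein_ca_idx(traj, chain)
  ref <- traj$frames[1L, idx, , drop = TRUE]
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    rmsd(traj$frames[i, idx, , drop = TRUE], ref)
  }, numeric(1))
  metric_series(vals, traj, chain, "protein_rmsd")
}

#' Per-frame ligand RMSD with respect to the protein
#'
#' Measures the displacement of the ligand in the protein frame of
#' reference: the superposition is determined by the chain's protein
#' C-alpha atoms ([fit_trajectory()]) and the ligand RMSD versus frame 1
#' is then computed without re-fitting on the ligand. Heavy atoms only by
#' default (hydrogens, if present, are excluded).
#'
#' @param traj a fitted [trajectory].
#' @param chain chain to measure.
#' @param ligand selector list for the ligand atoms (default: HETATM
#'   residue `"ASP"`, the bound aspartate substrate).
#' @param heavy_only drop atoms whose name starts with `H` (default TRUE).
#' @return metric-series data.frame.
#' @export
ligand_rmsd <- function(traj, chain = "A",
                        ligand = list(resid = "ASP", het = TRUE),
                        heavy_only = TRUE) {
  idx <- do.call(atom_indices, c(list(traj$topology, chain = chain), ligand))
  if (heavy_only && length(idx) > 0L) {
    idx <- idx[!startsWith(traj$topology$atoms$elety[idx], "H")]
  }
  if (length(idx) == 0L) stop("ligand selector matches no atoms in chain ", chain)
  ref <- traj$frames[1L, idx, , drop = FALSE][1, , , drop = TRUE]
  ref <- matrix(ref, ncol = 3)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    rmsd(matrix(traj$frames[i, idx, , drop = TRUE], ncol = 3), ref)
  }, numeric(1))
  metric_series(vals, traj, chain, "ligand_rmsd")
}

#' Per-residue root-mean-square fluctuation of C-alpha atoms
#'
#' RMSF of each residue's C-alpha around its time-mean position:
#' `sqrt(mean_t |x_t - mean_t(x)|^2)`, summed over the three Cartesian
#' axes. Requires a fitted trajectory with at least 2 frames.
#'
#' @param traj a fitted [trajectory].
#' @param chain chain to measure.
#' @return data.frame with `chain`, `resno`, `rmsf_A`.
#' @export
rmsf <- function(traj, chain = "A") {
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames")
  idx <- protein_ca_idx(traj, chain)
  x <- traj$frames[, idx, , drop = FALSE]
  mu <- apply(x, c(2, 3), mean)
  dev2 <- sweep(x, c(2, 3), mu)^2
  msf <- apply(dev2, 2, sum) / dim(x)[1]   # sum over frames & axes / n
  data.frame(chain = chain, resno = traj$topology$atoms$resno[idx],
             rmsf_A = sqrt(msf), stringsAsFactors = FALSE)
}

resolve_anchor <- function(topology, chain, anchor) {
  a <- topology$atoms
  hit <- a$resno == anchor$resno
  if (!is.null(anchor$elety)) hit <- hit & a$elety == anchor$elety
  if (!is.null(anchor$resid)) hit <- hit & a$resid == anchor$resid
  in_chain <- hit & a$chain == chain
  if (sum(in_chain) == 1L) return(which(in_chain))
  # Ions in real files sometimes carry their own chain label; if the
  # anchor is unique across the whole model, accept it regardless of chain.
  if (sum(in_chain) == 0L && sum(hit) == 1L) return(which(hit))
  stop(sprintf("cannot resolve anchor (resno=%s, atom=%s) in chain %s: %d matches",
               anchor$resno, anchor$elety %||% "*", chain, sum(in_chain)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-frame distance between two anchor atoms
#'
#' Euclidean distance in Angstrom between two atoms resolved in the given
#' chain, one value per frame. Anchors are lists with `resno` and
#' optionally `elety`/`resid`; monotopic ions that carry no chain label
#' are resolved by residue number across the model.
#'
#' @param traj a [trajectory] (fitting is unnecessary: distances are
#'   invariant under rigid transforms).
#' @param chain chain to measure.
#' @param anchor_a,anchor_b anchor selector lists.
#' @param metric_name label stored in the series.
#' @return metric-series data.frame.
#' @export
pair_distance <- function(traj, chain, anchor_a, anchor_b,
                          metric_name = "pair_distance") {
  ia <- resolve_anchor(traj$topology, chain, anchor_a)
  ib <- resolve_anchor(traj$topology, chain, anchor_b)
  delta <- matrix(traj$frames[, ia, ] - traj$frames[, ib, ], ncol = 3)
  d <- sqrt(rowSums(delta^2))
  metric_series(d, traj, chain, metric_name)
}

#' Preset gating and ion-coordination distance metrics
#'
#' Four per-chain distances characterize the state of each protomer:
#' * `hp2_opening` — HP1 tip (S366 C-alpha) to HP2 tip (G442 C-alpha);
#'   the extracellular-gate opening.
#' * `na1_dist` — Na+ ion with residue number 601 to D487 C-alpha.
#' * `na2_dist` — Na+ ion with residue number 603 to T396 C-alpha.
#' * `na3_dist` — Na+ ion with residue number 602 to D400 C-alpha.
#'
#' Residue anchors are configuration with these defaults; override via
#' [pair_distance()] for other numbering schemes.
#'
#' @param traj a [trajectory].
#' @param chain chain to measure.
#' @return metric-series data.frame.
#' @export
hp2_opening <- function(traj, chain = "A") {
  pair_distance(traj, chain, list(resno = 366L, elety = "CA"),
                list(resno = 442L, elety = "CA"), "hp2_opening")
}

#' @rdname hp2_opening
#' @param site sodium site, 1, 2 or 3.
#' @export
na_site_distance <- function(traj, chain = "A", site = 1L) {
  spec <- switch(as.character(site),
    "1" = list(ion = 601L, anchor = 487L, name = "na1_dist"),
    "2" = list(ion = 603L, anchor = 396L, name = "na2_dist"),
    "3" = list(ion = 602L, anchor = 400L, name = "na3_dist"),
    stop("site must be 1, 2 or 3"))
  pair_distance(traj, chain, list(resno = spec$ion, elety = "NA"),
                list(resno = spec$anchor, elety = "CA"), spec$name)
}

#' Flag an unstable chain system from its protein RMSD series
#'
#' A (replicate, chain) system is excluded from further analysis when its
#' protein RMSD reaches the threshold at any frame (`max >= threshold`);
#' 10 Angstrom by default. Exclusion bookkeeping is per chain, so a
#' replicate may contribute some chains and not others.
#'
#' @param series metric-series data.frame (or numeric vector) of protein
#'   RMSD values.
#' @param threshold_A exclusion threshold in Angstrom (default 10).
#' @return `TRUE` if the system must be excluded.
#' @export
flag_unstable <- function(series, threshold_A = 10) {
  vals <- if (is.data.frame(series)) series$value else as.numeric(series)
  if (length(vals) == 0L) stop("empty RMSD series")
  max(vals) >= threshold_A
}

#' Two-dimensional sampling-density landscape
#'
#' Normalized 2D histogram of two per-frame metrics (e.g. HP2 opening
#' versus ligand RMSD) pooled over all non-excluded chains and replicates
#' of one system, plus the two normalized 1D marginals. The density
#' integrates to 1 (sum of cells times bin area).
#'
#' @param x,y aligned per-frame metric values (same length).
#' @param nx,ny number of bins per axis.
#' @param xlim,ylim axis ranges (default: data range, padded when
#'   degenerate).
#' @return object of class `density_map`: `x_edges`, `y_edges`, `density`
#'   (nx x ny), `marginal_x`, `marginal_y`, `n_points`.
#' @export
sampling_density <- function(x, y, nx = 60L, ny = 60L,
                             xlim = NULL, ylim = NULL) {
  if (length(x) != length(y)) stop("x and y must be aligned per frame")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) == 0L) {
    stop("empty metric pool after exclusion; review the instability threshold")
  }
  pad_range <- function(r) if (diff(r) <= 0) r + c(-0.5, 0.5) else r
  xlim <- pad_range(xlim %||% range(x))
  ylim <- pad_range(ylim %||% range(y))
  xe <- seq(xlim[1], xlim[2], length.out = nx + 1L)
  ye <- seq(ylim[1], ylim[2], length.out = ny + 1L)
  ix <- pmin(pmax(findInterval(x, xe, rightmost.closed = TRUE), 1L), nx)
  iy <- pmin(pmax(findInterval(y, ye, rightmost.closed = TRUE), 1L), ny)
  counts <- matrix(0, nx, ny)
  tab <- table(factor(ix, levels = seq_len(nx)), factor(iy, levels = seq_len(ny)))
  counts[] <- as.numeric(tab)
  dx <- diff(xe)[1]; dy <- diff(ye)[1]
  dens <- counts / (length(x) * dx * dy)
  structure(list(
    x_edges = xe, y_edges = ye, density = dens,
    marginal_x = rowSums(dens) * dy,   # integrates over x to 1
    marginal_y = colSums(dens) * dx,
    n_points = length(x)
  ), class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d x %d bins, %d points\n",
              length(x$x_edges) - 1L, length(x$y_edges) - 1L, x$n_points))
  invisible(x)
}

#' Select representative frames at the most frequent gate opening
#'
#' Estimates the mode of the pooled HP2-opening distribution with a
#' histogram (Freedman-Diaconis bin width; the mode is the center of the
#' highest bin) and draws `k` frames uniformly at random among the frames
#' whose value falls inside the modal bin. If the bin holds fewer than
#' `k` frames the window is widened once to the two adjacent bins;
#' otherwise an error is raised. The selection is deterministic under
#' `seed`.
#'
#' @param pool data.frame with columns `replicate`, `chain`, `frame`,
#'   `value` (a pooled metric series, typically chain A of one system
#'   after exclusion), or a bare numeric vector.
#' @param k number of frames to select (default 5).
#' @param seed integer seed for the random draw (`NULL`: current RNG
#'   state).
#' @return object of class `frame_selection`: `frames` (selected rows),
#'   `mean_A`, `sd_A`, `mode_A`, `window_A`, `k`.
#' @export
select_representative_frames <- function(pool, k = 5L, seed = NULL) {
  if (!is.data.frame(pool)) {
    pool <- data.frame(replicate = NA_integer_, chain = NA_character_,
                       frame = seq_along(pool), value = as.numeric(pool))
  }
  vals <- pool$value
  if (length(vals) < k) stop("pool holds fewer than k frames")
  h <- graphics::hist(vals, breaks = "FD", plot = FALSE)
  i <- which.max(h$counts)
  window <- c(h$breaks[i], h$breaks[i + 1L])
  in_window <- function(w) {
    vals >= w[1] & (vals < w[2] | (w[2] >= max(h$breaks) & vals <= w[2]))
  }
  cand <- which(in_window(window))
  if (length(cand) < k) {
    window <- c(h$breaks[max(1L, i - 1L)],
                h$breaks[min(length(h$breaks), i + 2L)])
    cand <- which(in_window(window))
  }
  if (length(cand) < k) {
    stop(sprintf("only %d frames inside the modal window; cannot select %d",
                 length(cand), k))
  }
  sel <- local_seed_sample(cand, k, seed)
  picked <- pool[sel, , drop = FALSE]
  structure(list(
    frames = picked[order(picked$value), , drop = FALSE],
    mean_A = mean(picked$value), sd_A = stats::sd(picked$value),
    mode_A = mean(c(h$breaks[i], h$breaks[i + 1L])),
    window_A = window, k = as.integer(k)
  ), class = "frame_selection")
}

#' @export
print.frame_selection <- function(x, ...) {
  cat(sprintf("<frame_selection> %d frames, %.2f +/- %.2f A (mode %.2f A)\n",
              x$k, x$mean_A, x$sd_A, x$mode_A))
  invisible(x)
}

# Draw size elements of x under an optional seed without disturbing the
# caller's RNG stream.
local_seed_sample <- function(x, size, seed = NULL) {
  if (is.null(seed)) return(x[sample.int(length(x), size)])
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  x[sample.int(length(x), size)]
}

#' Export selected frames as single-model PDB files
#'
#' Writes each selected frame with the chain's protein atoms and the
#' originally coordinated Na+ ions (HETATM residue name `"NA"`), ready
#' for ensemble docking.
#'
#' @param selection a `frame_selection`.
#' @param trajs list of [trajectory] objects indexed by replicate id.
#' @param dir output directory (created if absent).
#' @param chain chain to export (default `"A"`).
#' @return character vector of written file paths.
#' @export
export_frames <- function(selection, trajs, dir, chain = "A") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  reps <- vapply(trajs, function(t) t$replicate_id, integer(1))
  paths <- character(0)
  for (i in seq_len(nrow(selection$frames))) {
    row <- selection$frames[i, ]
    traj <- trajs[[match(row$replicate, reps)]]
    keep <- sort(c(
      atom_indices(traj$topology, chain = chain, het = FALSE),
      atom_indices(traj$topology, chain = chain, resid = "NA", het = TRUE)
    ))
    atoms <- traj$topology$atoms[keep, , drop = FALSE]
    xyz <- traj$frames[row$frame, keep, , drop = TRUE]
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
    m <- structure_model(atoms, label = sprintf("%s rep%d frame%d",
                                                traj$system_label,
                                                row$replicate, row$frame))
    p <- file.path(dir, sprintf("%s_rep%02d_frame%04d.pdb",
                                traj$system_label, row$replicate, row$frame))
    write_pdb(m, p)
    paths <- c(paths, p)
  }
  paths
}

#' Analyze a set of replicate trajectories for one system
#'
#' Runs the full per-chain metric workflow: superposition onto frame 1,
#' protein and ligand RMSD, HP2 opening, the three sodium-site distances,
#' and the instability exclusion rule. Metrics of excluded
#' (replicate, chain) systems are retained in the output but marked, so
#' downstream pooling ([pool_metric()]) can drop them.
#'
#' @param trajs list of [trajectory] objects (replicates of one system).
#' @param chains chains to analyze (default all chains of the topology).
#' @param exclude_threshold_A instability threshold (default 10).
#' @param ligand ligand selector for [ligand_rmsd()]; `NULL` skips the
#'   ligand metric.
#' @return list with `metrics` (long data.frame of all series),
#'   `exclusions` (per replicate x chain: max protein RMSD and flag) and
#'   `rmsf` (per-residue fluctuations).
#' @export
analyze_trajectories <- function(trajs, chains = NULL,
                                 exclude_threshold_A = 10,
                                 ligand = list(resid = "ASP", het = TRUE)) {
  stopifnot(length(trajs) > 0L)
  if (is.null(chains)) {
    prot <- trajs[[1]]$topology$atoms
    chains <- sort(unique(prot$chain[!prot$het]))
  }
  metrics <- list(); excl <- list(); fluct <- list()
  for (traj in trajs) {
    for (ch in chains) {
      fitted <- fit_trajectory(traj, chain = ch)
      prmsd <- protein_rmsd(fitted, ch)
      excluded <- flag_unstable(prmsd, exclude_threshold_A)
      series <- list(prmsd,
                     hp2_opening(fitted, ch),
                     na_site_distance(fitted, ch, 1L),
                     na_site_distance(fitted, ch, 2L),
                     na_site_distance(fitted, ch, 3L))
      if (!is.null(ligand)) {
        series <- c(series, list(ligand_rmsd(fitted, ch, ligand)))
      }
      block <- do.call(rbind, series)
      block$excluded <- excluded
      metrics[[length(metrics) + 1L]] <- block
      excl[[length(excl) + 1L]] <- data.frame(
        system = traj$system_label, replicate = traj$replicate_id,
        chain = ch, max_protein_rmsd_A = max(prmsd$value),
        excluded = excluded, stringsAsFactors = FALSE)
      fl <- rmsf(fitted, ch)
      fl$system <- traj$system_label
      fl$replicate <- traj$replicate_id
      fluct[[length(fluct) + 1L]] <- fl
    }
  }
  list(metrics = do.call(rbind, metrics),
       exclusions = do.call(rbind, excl),
       rmsf = do.call(rbind, fluct))
}

#' Pool one metric across non-excluded chains and replicates
#'
#' @param analysis result of [analyze_trajectories()].
#' @param metric metric name (e.g. `"hp2_opening"`).
#' @param chains chains to pool (default: all).
#' @param include_excluded keep flagged systems (default FALSE).
#' @return data.frame with `replicate`, `chain`, `frame`, `value`.
#' @export
pool_metric <- function(analysis, metric, chains = NULL,
                        include_excluded = FALSE) {
  m <- analysis$metrics
  keep <- m$metric == metric
  if (!is.null(chains)) keep <- keep & m$chain %in% chains
  if (!include_excluded) keep <- keep & !m$excluded
  out <- m[keep, c("replicate", "chain", "frame", "value")]
  if (nrow(out) == 0L) {
    stop("empty metric pool after exclusion; review the instability threshold")
  }
  rownames(out) <- NULL
  out
}
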