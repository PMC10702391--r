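# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Generators are bit-reproducible under a seed
# without disturbing unrelated randomness.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
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
  force(code)
}

#' Specification for the synthetic trajectory generator
#'
#' Declares the planted ground truth for a set of replicate MD-like
#' trajectories of a trimeric gate system: the per-chain HP2-opening
#' distance is drawn from a Gaussian with the given mean and standard
#' deviation, global rigid tumbling is added (removed again by
#' superposition), and designated (replicate, chain) systems receive a
#' growing internal deformation that drives their protein RMSD past the
#' instability threshold.
#'
#' @param n_frames frames per trajectory (>= 2).
#' @param dt_ps frame spacing, picoseconds.
#' @param n_replicates number of replicate trajectories.
#' @param chains chain identifiers (default A, B, C — a trimer).
#' @param gate_mean_A,gate_sd_A planted HP2-opening distribution (Angstrom).
#' @param ligand_mode `"stable"` (ligand co-moves with its chain) or
#'   `"drift"` (Brownian walk of the whole ligand).
#' @param ligand_drift_rate_A_ns drift scale when `ligand_mode = "drift"`.
#' @param unstable_replicates replicates rendered unstable: an integer
#'   vector (all chains of those replicates) or a data.frame with columns
#'   `replicate`, `chain`.
#' @param unstable_target_A final-frame deformation amplitude (default 12,
#'   safely past the 10 Angstrom exclusion threshold).
#' @param ion_escape optional list(site, frame): after `frame`, the ion of
#'   that sodium site walks away from its coordinating atom.
#' @param thermal_sd_A isotropic per-atom thermal jitter (Angstrom).
#' @param system_label system name stored on each trajectory.
#' @param seed integer seed; all generator randomness flows from it.
#' @return validated spec list of class `traj_gen_spec`.
#' @export
traj_gen_spec <- function(n_frames = 500L, dt_ps = 500, n_replicates = 10L,
                          chains = c("A", "B", "C"),
                          gate_mean_A = 6, gate_sd_A = 0.2,
                          ligand_mode = c("stable", "drift"),
                          ligand_drift_rate_A_ns = 0.5,
                          unstable_replicates = NULL,
                          unstable_target_A = 12,
                          ion_escape = NULL,
                          thermal_sd_A = 0.03,
                          system_label = "WT", seed = 1L) {
  ligand_mode <- match.arg(ligand_mode)
  if (n_frames < 2L) stop("invalid spec: n_frames must be >= 2")
  if (gate_sd_A < 0) stop("invalid spec: gate_sd_A must be >= 0")
  if (dt_ps <= 0) stop("invalid spec: dt_ps must be positive")
  if (is.numeric(unstable_replicates)) {
    unstable_replicates <- expand.grid(replicate = as.integer(unstable_replicates),
                                       chain = chains,
                                       stringsAsFactors = FALSE)
  }
  structure(list(n_frames = as.integer(n_frames), dt_ps = dt_ps,
                 n_replicates = as.integer(n_replicates), chains = chains,
                 gate_mean_A = gate_mean_A, gate_sd_A = gate_sd_A,
                 ligand_mode = ligand_mode,
                 ligand_drift_rate_A_ns = ligand_drift_rate_A_ns,
                 unstable = unstable_replicates,
                 unstable_target_A = unstable_target_A,
                 ion_escape = ion_escape, thermal_sd_A = thermal_sd_A,
                 system_label = system_label, seed = as.integer(seed)),
            class = "traj_gen_spec")
}

# Deterministic toy protomer: ~56 C-alpha atoms covering the metric
# anchors (366, 442, 396, 400, 487), three Na+ ions (601-603) and an
# aspartate ligand. Not a realistic fold -- just enough named geometry for
# every metric.
chain_template <- function() {
  seg <- function(resnos, origin, step, wob) {
    k <- seq_along(resnos) - 1
    data.frame(resno = resnos,
               x = origin[1] + step * k,
               y = origin[2] + 1.2 * sin(wob * k),
               z = origin[3] + 1.2 * cos(wob * k))
  }
  prot <- rbind(
    seg(358:372, c(0, 0, 0), 1.5, 0.7),        # HP1 region incl. 366
    seg(436:450, c(0.5, 8, 4), 1.5, 0.6),      # HP2 region incl. 442
    seg(392:404, c(-5, -6, 2), 1.5, 0.8),      # Na2/Na3 coordinating span
    seg(478:490, c(6, -7, -3), 1.5, 0.65)      # Na1 coordinating span
  )
  prot$chain <- "A"; prot$resid <- "GLY"; prot$elety <- "CA"; prot$het <- FALSE
  ca <- function(rn) unlist(prot[prot$resno == rn, c("x", "y", "z")])
  ions <- data.frame(
    resno = c(601L, 603L, 602L),
    rbind(ca(487) + c(1.5, 1.0, 0.5),
          ca(396) + c(-1.2, 1.8, 0.8),
          ca(400) + c(0.9, -1.4, 1.1)),
    chain = "A", resid = "NA", elety = "NA", het = TRUE)
  lig_center <- (ca(366) + ca(442)) / 2 + c(1, -1, 0.5)
  lig_off <- rbind(N = c(0, 1.4, 0), CA = c(0, 0, 0), C = c(1.3, -0.6, 0),
                   O = c(2.3, 0.1, 0.3), CB = c(-1.2, -0.8, 0.6),
                   CG = c(-2.5, -0.1, 0.4), OD1 = c(-3.4, -0.8, 0),
                   OD2 = c(-2.8, 1.1, 0.6))
  lig <- data.frame(resno = 700L,
                    x = lig_center[1] + lig_off[, 1],
                    y = lig_center[2] + lig_off[, 2],
                    z = lig_center[3] + lig_off[, 3],
                    chain = "A", resid = "ASP",
                    elety = rownames(lig_off), het = TRUE)
  rbind(prot[, c("chain", "resno", "resid", "elety", "x", "y", "z", "het")],
        ions[, c("chain", "resno", "resid", "elety", "x", "y", "z", "het")],
        lig[, c("chain", "resno", "resid", "elety", "x", "y", "z", "het")])
}

trimer_topology <- function(chains, label) {
  offsets <- list(c(0, 0, 0), c(40, 0, 0), c(20, 35, 0), c(-40, 0, 0),
                  c(0, -40, 0))
  parts <- lapply(seq_along(chains), function(i) {
    a <- chain_template()
    a$chain <- chains[i]
    off <- offsets[[((i - 1L) %% length(offsets)) + 1L]]
    a$x <- a$x + off[1]; a$y <- a$y + off[2]; a$z <- a$z + off[3]
    a
  })
  structure_model(do.call(rbind, parts), label = label)
}

random_rotation <- function(angle_sd_rad) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::rnorm(1, 0, angle_sd_rad)
  k <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

#' Generate synthetic replicate trajectories with planted ground truth
#'
#' Builds a toy trimeric topology ([traj_gen_spec()] describes the
#' planted conditions) and emits one [trajectory] per replicate. The
#' generator is the statistical inverse of the trajectory-metric stage:
#' the measured HP2-opening distribution matches the planted Gaussian,
#' unstable systems exceed the RMSD exclusion threshold by construction,
#' and everything is bit-reproducible under the spec seed.
#'
#' @param spec a `traj_gen_spec`.
#' @return list of [trajectory] objects (length `n_replicates`).
#' @export
gen_trajectory <- function(spec) {
  stopifnot(inherits(spec, "traj_gen_spec"))
  with_local_seed(spec$seed, {
    topo <- trimer_topology(spec$chains, paste0(spec$system_label, " synthetic"))
    base <- coords(topo)
    n_atoms <- nrow(base)
    at <- topo$atoms
    chain_idx <- lapply(spec$chains, function(ch) which(at$chain == ch))
    names(chain_idx) <- spec$chains
    gate_from <- vapply(spec$chains, function(ch) {
      select_atom(topo, ch, 366L, "CA")$index }, integer(1))
    gate_to <- vapply(spec$chains, function(ch) {
      select_atom(topo, ch, 442L, "CA")$index }, integer(1))
    lig_idx <- lapply(spec$chains, function(ch) {
      atom_indices(topo, chain = ch, resid = "ASP", het = TRUE)
    })
    prot_idx <- lapply(spec$chains, function(ch) {
      atom_indices(topo, chain = ch, het = FALSE)
    })
    ion_resno <- c("1" = 601L, "2" = 603L, "3" = 602L)

    lapply(seq_len(spec$n_replicates), function(rep_i) {
      fr <- array(0, dim = c(spec$n_frames, n_atoms, 3L))
      rot <- diag(3)
      trans <- c(0, 0, 0)
      lig_disp <- lapply(spec$chains, function(ch) c(0, 0, 0))
      step_sd <- spec$ligand_drift_rate_A_ns * sqrt(spec$dt_ps / 1000)
      unstable_chains <- character(0)
      if (!is.null(spec$unstable)) {
        unstable_chains <-
          spec$unstable$chain[spec$unstable$replicate == rep_i]
      }
      for (t in seq_len(spec$n_frames)) {
        x <- base
        for (ci in seq_along(spec$chains)) {
          ch <- spec$chains[ci]
          # plant the gate distance: HP2 tip placed on the fixed axis
          d <- stats::rnorm(1, spec$gate_mean_A, spec$gate_sd_A)
          u <- base[gate_to[ci], ] - base[gate_from[ci], ]
          u <- u / sqrt(sum(u^2))
          x[gate_to[ci], ] <- x[gate_from[ci], ] + u * d
          if (spec$ligand_mode == "drift") {
            lig_disp[[ci]] <- lig_disp[[ci]] + stats::rnorm(3, 0, step_sd)
            x[lig_idx[[ci]], ] <-
              sweep(x[lig_idx[[ci]], , drop = FALSE], 2, lig_disp[[ci]], "+")
          }
          if (ch %in% unstable_chains && t > 1L) {
            amp <- spec$unstable_target_A * (t - 1) / (spec$n_frames - 1)
            idx <- prot_idx[[ci]]
            sgn <- rep_len(c(1, -1), length(idx))
            sgn <- sgn - mean(sgn)
            x[idx, 3] <- x[idx, 3] + amp * sgn
          }
        }
        if (!is.null(spec$ion_escape) && t > spec$ion_escape$frame) {
          rn <- ion_resno[[as.character(spec$ion_escape$site)]]
          esc <- atom_indices(topo, chain = spec$chains[1], resno = rn,
                              het = TRUE)
          x[esc, ] <- x[esc, ] +
            0.2 * (t - spec$ion_escape$frame) * c(1, 1, 1) / sqrt(3)
        }
        if (spec$thermal_sd_A > 0) {
          x <- x + matrix(stats::rnorm(length(x), 0, spec$thermal_sd_A),
                          nrow = n_atoms)
        }
        # cumulative global tumbling, removed downstream by superposition
        rot <- rot %*% random_rotation(2 * pi / 180)
        trans <- trans + stats::rnorm(3, 0, 0.5)
        fr[t, , ] <- sweep(x %*% rot, 2, trans, "+")
      }
      trajectory(topo, fr, dt_ps = spec$dt_ps, replicate_id = rep_i,
                 system_label = spec$system_label)
    })
  })
}
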