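test_that("trajectory generation is bit-identical under a seed", {
  spec <- traj_gen_spec(n_frames = 20, n_replicates = 2, seed = 5)
  a <- gen_trajectory(spec)
  b <- gen_trajectory(spec)
  expect_identical(a[[1]]$frames, b[[1]]$frames)
  expect_identical(a[[2]]$frames, b[[2]]$frames)
  c_ <- gen_trajectory(traj_gen_spec(n_frames = 20, n_replicates = 2,
                                     seed = 6))
  expect_false(identical(a[[1]]$frames, c_[[1]]$frames))
})

test_that("the planted gate distribution is recovered by the metric", {
  spec <- traj_gen_spec(n_frames = 400, n_replicates = 2, gate_mean_A = 6,
                        gate_sd_A = 0.2, seed = 9)
  trajs <- gen_trajectory(spec)
  pooled <- unlist(lapply(trajs, function(tr) {
    unlist(lapply(c("A", "B", "C"), function(ch) {
      hp2_opening(fit_trajectory(tr, ch), ch)$value
    }))
  }))
  expect_equal(mean(pooled), 6.0, tolerance = 0.1)
  expect_equal(sd(pooled), 0.2, tolerance = 0.05)
})

test_that("unstable replicates cross the exclusion threshold by construction", {
  spec <- traj_gen_spec(n_frames = 80, n_replicates = 3, gate_mean_A = 6,
                        unstable_replicates = 2L, seed = 13)
  trajs <- gen_trajectory(spec)
  res <- analyze_trajectories(trajs)
  excl <- res$exclusions
  expect_true(all(excl$excluded[excl$replicate == 2]))   # all chains
  expect_false(any(excl$excluded[excl$replicate != 2]))
  expect_true(all(excl$max_protein_rmsd_A[excl$replicate == 2] >= 10))
})

test_that("ligand drift produces growing displacement, stable mode does not", {
  drift_spec <- traj_gen_spec(n_frames = 300, n_replicates = 1,
                              ligand_mode = "drift",
                              ligand_drift_rate_A_ns = 2, seed = 3)
  tr <- gen_trajectory(drift_spec)[[1]]
  lr <- ligand_rmsd(fit_trajectory(tr, "A"), "A")
  early <- mean(lr$value[2:50])
  late <- mean(lr$value[251:300])
  expect_gt(late, early)

  stable <- gen_trajectory(traj_gen_spec(n_frames = 300, n_replicates = 1,
                                         ligand_mode = "stable", seed = 3))[[1]]
  ls <- ligand_rmsd(fit_trajectory(stable, "A"), "A")
  expect_lt(max(ls$value), 0.5)
})

test_that("ion escape moves the planted sodium away after the set frame", {
  spec <- traj_gen_spec(n_frames = 120, n_replicates = 1,
                        ion_escape = list(site = 2, frame = 60), seed = 4)
  tr <- gen_trajectory(spec)[[1]]
  d <- na_site_distance(tr, "A", 2)$value
  expect_gt(mean(d[100:120]) - mean(d[1:60]), 5)
  # the other sites stay put
  d1 <- na_site_distance(tr, "A", 1)$value
  expect_lt(abs(mean(d1[100:120]) - mean(d1[1:60])), 0.5)
})

test_that("generator specs validate their invariants", {
  expect_error(traj_gen_spec(n_frames = 1), "n_frames")
  expect_error(traj_gen_spec(gate_sd_A = -1), "gate_sd_A")
  expect_error(plate_gen_spec(concentrations_M = c(1e-5, 2e-5, 3e-5)),
               ">= 4 distinct")
  expect_error(plate_gen_spec(noise_sd_pct = -5), "noise")
  expect_error(plate_gen_spec(shape = "bell", mode = "inhibition"),
               "bell")
})

test_that("noiseless plates round-trip the planted nCI and potency exactly", {
  spec <- plate_gen_spec(true_p_potency = 4.0, true_emax_pct = 90,
                         true_hill = 1.3, noise_sd_pct = 0,
                         n_experiments = 1, seed = 10)
  p <- gen_plate(spec)[[1]]
  # forward CI -> nCI pass reproduces the generator's planted nCI
  tr <- p$traces[p$traces$well == "W01", ]
  ci <- cell_index(tr$impedance_ohm, p$z0_ohm[["W01"]])
  nci <- normalize_ci(ci, tr$time_min, p$events$t_stimulate_min)
  expect_equal(nci, p$meta$nci_planted[, "W01"], tolerance = 1e-12,
               ignore_attr = TRUE)
  q <- quantify_experiment(p)
  expect_equal(q$fit$p_potency, 4.0, tolerance = 1e-3)
  expect_equal(q$fit$emax_pct, 90, tolerance = 0.1)
  # measured responses equal the planted curve
  planted <- planted_response(spec, q$responses$conc_M)
  expect_equal(q$responses$response_pct, planted, tolerance = 1e-6)
})

test_that("plate generation is deterministic under a seed", {
  spec <- plate_gen_spec(seed = 21)
  a <- gen_plate(spec)[[1]]
  b <- gen_plate(spec)[[1]]
  expect_identical(a$traces$impedance_ohm, b$traces$impedance_ohm)
})

test_that("flat and bell specs drive the matching pathology flags", {
  flat <- recover_potency(plate_gen_spec(shape = "flat", noise_sd_pct = 5,
                                         seed = 31))
  expect_true(flat$summary$flags$not_determined)
  expect_equal(flat$summary$n, 0L)
  bell <- recover_potency(plate_gen_spec(shape = "bell",
                                         true_p_potency = 5.8,
                                         true_emax_pct = 70, true_hill = 1.5,
                                         noise_sd_pct = 5, seed = 32))
  expect_true(bell$summary$flags$bell_shaped)
})

test_that("synthetic variant tables carry their planted truth", {
  g <- gen_variant_table(n_patients = 40, positions_pool = c(127, 446, 479),
                         recurrence = 0.5, seed = 2)
  expect_equal(g$truth$n_unique, 3L)
  expect_equal(nrow(g$table), g$truth$n_mutations)
  parsed <- parse_variant_table(g$table)
  expect_equal(nrow(parsed$errors), 0L)
  expect_equal(length(unique_missense(parsed$records, "SLC1A3")),
               g$truth$n_unique)
  expect_equal(frequency_percent(g$truth$n_unique, 40), 100 * 3 / 40)
  # per-change recurrence matches the planted counts
  counts <- table(g$table$protein_change)
  expect_equal(as.integer(counts[names(g$truth$counts)]),
               unname(g$truth$counts))
  expect_identical(gen_variant_table(40, c(127, 446, 479), 0.5, seed = 2)$table,
                   g$table)
})
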