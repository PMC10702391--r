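make_chain_model <- function(n = 8) {
  set.seed(11)
  structure_model(data.frame(
    chain = "A", resno = seq_len(n), resid = "GLY", elety = "CA",
    x = cumsum(runif(n, 1, 2)), y = sin(seq_len(n)), z = cos(seq_len(n) / 2),
    het = FALSE), label = "chain")
}

test_that("fitting leaves a static trajectory unchanged and undoes tumbling", {
  m <- make_chain_model()
  x <- coords(m)
  static <- toy_trajectory(m, list(x, x, x))
  fitted <- fit_trajectory(static, "A")
  expect_equal(fitted$frames, static$frames, tolerance = 1e-9)

  set.seed(5)
  tumbling <- toy_trajectory(m, lapply(1:4, function(i) {
    sweep(x %*% random_rotation_matrix(), 2, rnorm(3, sd = 8), "+")
  }))
  ft <- fit_trajectory(tumbling, "A")
  for (i in 2:4) {
    expect_equal(ft$frames[i, , ], ft$frames[1, , ], tolerance = 1e-9)
  }
})

test_that("per-frame RMSD after fitting matches the optimal-superposition oracle", {
  m <- make_chain_model(7)
  x <- coords(m)
  set.seed(9)
  internal <- lapply(1:3, function(i) {
    moved <- x + matrix(rnorm(length(x), sd = 0.4), nrow(x), 3)
    sweep(moved %*% random_rotation_matrix(), 2, rnorm(3, sd = 5), "+")
  })
  tr <- toy_trajectory(m, c(list(x), internal))
  series <- protein_rmsd(fit_trajectory(tr, "A"), "A")
  expect_equal(series$value[1], 0)
  for (i in 2:4) {
    expect_equal(series$value[i], oracle_min_rmsd(internal[[i - 1]], x),
                 tolerance = 1e-6)
  }
})

test_that("protein RMSD reproduces hand-computable displacements", {
  m <- make_chain_model()
  x <- coords(m)
  tr <- toy_trajectory(m, list(x, sweep(x, 2, c(1, 0, 0), "+")))
  # uniform displacement is removed by fitting; measure unfitted
  series <- protein_rmsd(tr, "A")
  expect_equal(series$value, c(0, 1))
  set.seed(2)
  rnd <- x + matrix(rnorm(length(x), sd = 0.8), nrow(x), 3)
  tr2 <- toy_trajectory(m, list(x, rnd))
  expect_equal(protein_rmsd(tr2, "A")$value[2], oracle_rmsd(rnd, x),
               tolerance = 1e-12)
})

test_that("ligand RMSD is measured in the protein frame without re-fitting", {
  at <- rbind(
    data.frame(chain = "A", resno = 1:6, resid = "GLY", elety = "CA",
               x = c(0, 2, 4, 6, 8, 10), y = c(0, 1, 0, 1, 0, 1),
               z = c(0, 0, 1, 1, 0, 0), het = FALSE),
    data.frame(chain = "A", resno = 700L, resid = "ASP",
               elety = c("CA", "CB"), x = c(3, 4), y = c(3, 3), z = c(2, 2),
               het = TRUE))
  m <- structure_model(at)
  x <- coords(m)
  # frame 2: whole system rigidly moved, ligand co-moving -> 0
  set.seed(4)
  rot <- random_rotation_matrix()
  co_moving <- sweep(x %*% rot, 2, c(3, -2, 1), "+")
  # frame 3: protein fixed, ligand translated by 2 A
  lig_moved <- x
  lig_moved[7:8, 1] <- lig_moved[7:8, 1] + 2
  tr <- fit_trajectory(toy_trajectory(m, list(x, co_moving, lig_moved)), "A")
  lr <- ligand_rmsd(tr, "A")
  expect_equal(lr$value[2], 0, tolerance = 1e-9)
  expect_equal(lr$value[3], 2, tolerance = 1e-9)
  expect_error(ligand_rmsd(tr, "A", ligand = list(resid = "XYZ", het = TRUE)),
               "no atoms")
})

test_that("RMSF matches closed forms for static, sinusoidal and noisy atoms", {
  m <- make_chain_model(5)
  x <- coords(m)
  static <- toy_trajectory(m, list(x, x, x))
  expect_equal(rmsf(static, "A")$rmsf_A, rep(0, 5), tolerance = 1e-12)

  # atom 1 oscillating along x with amplitude a over whole periods: a/sqrt(2)
  a <- 1.7
  n <- 1000L
  phases <- 2 * pi * (seq_len(n) - 1) / n * 10   # 10 full periods
  frames <- lapply(phases, function(p) {
    y <- x; y[1, 1] <- y[1, 1] + a * sin(p); y
  })
  fl <- rmsf(toy_trajectory(m, frames), "A")
  expect_equal(fl$rmsf_A[1], a / sqrt(2), tolerance = 0.02 * a)
  expect_equal(fl$rmsf_A[-1], rep(0, 4), tolerance = 1e-12)

  # isotropic white noise sd sigma per axis: sqrt(3) * sigma
  sigma <- 0.5
  set.seed(21)
  noisy <- lapply(seq_len(1000), function(i) {
    x + matrix(rnorm(length(x), sd = sigma), nrow(x), 3)
  })
  fl2 <- rmsf(toy_trajectory(m, noisy), "A")
  expect_equal(mean(fl2$rmsf_A), sqrt(3) * sigma,
               tolerance = 0.05 * sqrt(3) * sigma)
  # direct per-atom oracle on a small slice
  mat1 <- t(vapply(seq_len(1000), function(i) noisy[[i]][1, ], numeric(3)))
  expect_equal(fl2$rmsf_A[1], oracle_rmsf(mat1), tolerance = 1e-9)
  expect_error(rmsf(toy_trajectory(m, list(x)), "A"), "at least 2")
})

test_that("pair distances and presets resolve anchors and match by hand", {
  m <- toy_anchor_model()
  x <- coords(m)
  x2 <- x
  x2[2, ] <- x2[1, ] + c(3, 4, 0)      # 442 CA placed 5 A from 366 CA
  tr <- toy_trajectory(m, list(x, x2))
  gate <- hp2_opening(tr, "A")
  expect_equal(gate$value[1], oracle_dist(x[1, ], x[2, ]), tolerance = 1e-12)
  expect_equal(gate$value[2], 5)

  x3 <- x
  x3[2, ] <- x3[1, ]                    # coincident anchors
  expect_equal(hp2_opening(toy_trajectory(m, list(x3)), "A")$value, 0)

  for (site in 1:3) {
    d <- na_site_distance(tr, "A", site)
    ion_row <- c("1" = 6L, "2" = 8L, "3" = 7L)[[as.character(site)]]
    ca_row <- c("1" = 4L, "2" = 5L, "3" = 3L)[[as.character(site)]]
    expect_equal(d$value[1], oracle_dist(x[ion_row, ], x[ca_row, ]),
                 tolerance = 1e-12)
  }
  expect_error(pair_distance(tr, "A", list(resno = 9999L), list(resno = 366L)),
               "cannot resolve")
})

test_that("distance metrics are invariant under global rigid transforms", {
  m <- toy_anchor_model()
  x <- coords(m)
  set.seed(14)
  moved <- sweep(x %*% random_rotation_matrix(), 2, c(12, -7, 3), "+")
  d1 <- hp2_opening(toy_trajectory(m, list(x)), "A")$value
  d2 <- hp2_opening(toy_trajectory(m, list(moved)), "A")$value
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("the instability rule excludes at the threshold, monotonically", {
  expect_false(flag_unstable(c(1, 4, 9.9)))
  expect_true(flag_unstable(c(1, 4, 10.0)))
  expect_true(flag_unstable(c(12, 1, 1)))
  expect_error(flag_unstable(numeric(0)), "empty")
  # raising the threshold never excludes more systems
  set.seed(8)
  for (i in 1:20) {
    series <- runif(50, 0, 15)
    thresholds <- sort(runif(5, 5, 14))
    flags <- vapply(thresholds, function(th) flag_unstable(series, th),
                    logical(1))
    expect_true(all(diff(as.integer(flags)) <= 0))
  }
})

test_that("sampling density normalizes and localizes planted structure", {
  d1 <- sampling_density(c(3), c(7), nx = 10, ny = 10)
  area <- diff(d1$x_edges)[1] * diff(d1$y_edges)[1]
  expect_equal(sum(d1$density) * area, 1, tolerance = 1e-9)
  expect_equal(sum(d1$density > 0), 1L)   # single point: one occupied bin

  set.seed(33)
  n <- 4000
  cl <- rbind(cbind(rnorm(n, 5, 0.25), rnorm(n, 1, 0.25)),
              cbind(rnorm(n, 9, 0.25), rnorm(n, 3, 0.25)))
  dm <- sampling_density(cl[, 1], cl[, 2], nx = 40, ny = 40)
  dx <- diff(dm$x_edges)[1]; dy <- diff(dm$y_edges)[1]
  expect_equal(sum(dm$density) * dx * dy, 1, tolerance = 1e-9)
  # marginals integrate to 1
  expect_equal(sum(dm$marginal_x) * dx, 1, tolerance = 1e-9)
  expect_equal(sum(dm$marginal_y) * dy, 1, tolerance = 1e-9)
  # each planted cluster produces a local maximum within a bin of its center
  centers_x <- (dm$x_edges[-1] + head(dm$x_edges, -1)) / 2
  centers_y <- (dm$y_edges[-1] + head(dm$y_edges, -1)) / 2
  for (ctr in list(c(5, 1), c(9, 3))) {
    half <- dm$density
    half[abs(centers_x - ctr[1]) > 2, ] <- 0   # restrict to the cluster side
    peak <- arrayInd(which.max(half), dim(half))
    expect_equal(c(centers_x[peak[1]], centers_y[peak[2]]), ctr,
                 tolerance = 2 * max(dx, dy), ignore_attr = TRUE)
  }
  expect_error(sampling_density(numeric(0), numeric(0)), "empty")
})

test_that("representative-frame selection is modal, seeded and windowed", {
  # all frames at the same distance: any 5, mean d, sd 0
  sel <- select_representative_frames(rep(6.25, 40), k = 5, seed = 1)
  expect_equal(nrow(sel$frames), 5L)
  expect_equal(sel$mean_A, 6.25)
  expect_equal(sel$sd_A, 0)

  set.seed(55)
  pool <- data.frame(replicate = rep(1:5, each = 400), chain = "A",
                     frame = rep(1:400, 5),
                     value = rnorm(2000, 10.5, 0.2))
  s1 <- select_representative_frames(pool, k = 5, seed = 99)
  s2 <- select_representative_frames(pool, k = 5, seed = 99)
  expect_identical(s1$frames, s2$frames)      # determinism under a seed
  expect_equal(s1$mean_A, 10.5, tolerance = 0.2)
  # selected values always lie inside the reported window
  expect_true(all(s1$frames$value >= s1$window_A[1] &
                    s1$frames$value <= s1$window_A[2]))
  expect_error(select_representative_frames(rnorm(3), k = 5), "fewer than k")
})

test_that("analysis pooling drops excluded systems", {
  spec <- traj_gen_spec(n_frames = 60, n_replicates = 2, gate_mean_A = 6,
                        gate_sd_A = 0.2,
                        unstable_replicates = data.frame(replicate = 2L,
                                                         chain = "A"),
                        seed = 18)
  res <- analyze_trajectories(gen_trajectory(spec))
  excl <- res$exclusions
  expect_true(excl$excluded[excl$replicate == 2 & excl$chain == "A"])
  expect_equal(sum(excl$excluded), 1L)
  pooled <- pool_metric(res, "hp2_opening", chains = "A")
  expect_false(any(pooled$replicate == 2))
  full <- pool_metric(res, "hp2_opening", chains = "A",
                      include_excluded = TRUE)
  expect_true(any(full$replicate == 2))
})
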