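test_that("single-model PDB parsing preserves atoms, order and identity", {
  m <- read_pdb(fixture_path("toy_site.pdb"))
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 9L)
  expect_equal(m$atoms$resno[1], 366L)
  expect_true(m$atoms$het[5])          # sodium ion is a first-class atom
  expect_equal(m$atoms$resid[5], "NA")
  expect_equal(sort(unique(m$atoms$chain)), c("A", "B"))
})

test_that("multi-model PDB yields one frame per MODEL with shared topology", {
  tr <- read_multimodel_pdb(fixture_path("toy_traj.pdb"))
  expect_s3_class(tr, "trajectory")
  expect_equal(n_frames(tr), 2L)
  expect_equal(dim(tr$frames)[2], 9L)
  expect_equal(tr$frames[2, , ] - tr$frames[1, , ],
               matrix(1.5, 9, 3), ignore_attr = TRUE)
})

test_that("write/read round trip preserves coordinates to format precision", {
  m <- read_pdb(fixture_path("toy_site.pdb"))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, f)
  m2 <- read_pdb(f)
  expect_equal(coords(m2), coords(m), tolerance = 1e-8)
  expect_identical(m2$atoms[, c("chain", "resno", "resid", "elety", "het")],
                   m$atoms[, c("chain", "resno", "resid", "elety", "het")])

  # trajectory round trip, including non-integral coordinates
  set.seed(42)
  fr <- list(coords(m), coords(m) + matrix(rnorm(27), 9, 3))
  tr <- toy_trajectory(m, fr)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(tr, f2)
  tr2 <- read_multimodel_pdb(f2)
  expect_equal(tr2$frames, tr$frames, tolerance = 1e-3)
})

test_that("the reader agrees with an independent PDB parser", {
  skip_if_not_installed("bio3d")
  m <- read_pdb(fixture_path("toy_site.pdb"))
  b <- bio3d::read.pdb(fixture_path("toy_site.pdb"))
  expect_equal(unname(coords(m)[, 1]), b$atom$x)
  expect_equal(unname(coords(m)[, 2]), b$atom$y)
  expect_equal(m$atoms$resno, b$atom$resno)
  expect_equal(m$atoms$elety, b$atom$elety)
})

test_that("malformed records are rejected with informative errors", {
  lines <- readLines(fixture_path("toy_site.pdb"))
  bad <- lines
  bad[3] <- sub("   4.800", "  4.8o00", bad[3])
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, f)
  expect_error(read_pdb(f), "line 3")

  ins <- lines
  substr(ins[2], 27, 27) <- "A"
  writeLines(ins, f)
  expect_error(read_pdb(f), "insertion code")

  expect_error(read_pdb(withr::local_tempfile(fileext = ".pdb")), "not found")
})

test_that("inconsistent atom counts across models raise a topology error", {
  tr_lines <- readLines(fixture_path("toy_traj.pdb"))
  # drop one atom from the second model
  second_atoms <- which(startsWith(tr_lines, "ATOM") |
                          startsWith(tr_lines, "HETATM"))
  drop <- second_atoms[second_atoms > which(startsWith(tr_lines, "MODEL"))[2]][1]
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(tr_lines[-drop], f)
  expect_error(read_multimodel_pdb(f), "topology error")
})

test_that("atom selection returns exactly one atom or a typed error", {
  m <- read_pdb(fixture_path("toy_site.pdb"))
  a <- select_atom(m, "A", 366, "CA")
  expect_equal(a$resid, "SER")
  expect_equal(a$index, 1L)
  # sodium addressed by residue number
  ion <- select_atom(m, "A", 601, "NA")
  expect_true(ion$het)
  expect_error(select_atom(m, "A", 999, "CA"), "lookup error")
  # chain-agnostic query for resno 366 matches chains A and B
  expect_error(select_atom(m, NA, 366, "CA"), "integrity error")
})

test_that("Kabsch superposition recovers exact transforms", {
  m <- coords(read_pdb(fixture_path("toy_site.pdb")))
  sp <- superpose(m, m)
  expect_equal(sp$rmsd_fit, 0, tolerance = 1e-12)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)

  shifted <- sweep(m, 2, c(5, 0, 0), "+")
  sp2 <- superpose(shifted, m)
  expect_equal(sp2$rmsd_fit, 0, tolerance = 1e-10)
  expect_equal(sp2$fitted, m, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(det(sp2$rotation), 1, tolerance = 1e-12)
})

test_that("superposition matches brute-force rotational minimization", {
  set.seed(101)
  for (rep in 1:3) {
    ref <- matrix(rnorm(8 * 3, sd = 3), 8, 3)
    rot <- random_rotation_matrix()
    mob <- sweep(ref %*% rot, 2, rnorm(3, sd = 4), "+") +
      matrix(rnorm(24, sd = 0.1), 8, 3)
    sp <- superpose(mob, ref)
    expect_equal(sp$rmsd_fit, oracle_min_rmsd(mob, ref), tolerance = 1e-6)
  }
})

test_that("superposition RMSD is invariant to prior rigid transforms", {
  set.seed(7)
  ref <- matrix(rnorm(10 * 3, sd = 2), 10, 3)
  mob <- ref + matrix(rnorm(30, sd = 0.3), 10, 3)
  base <- superpose(mob, ref)$rmsd_fit
  for (rep in 1:5) {
    moved <- sweep(mob %*% random_rotation_matrix(), 2, rnorm(3, sd = 10), "+")
    expect_equal(superpose(moved, ref)$rmsd_fit, base, tolerance = 1e-9)
  }
})

test_that("degenerate fit subsets are rejected", {
  ref <- matrix(rnorm(12), 4, 3)
  expect_error(superpose(ref, ref, fit_idx = 1:2), "at least 3")
  line <- cbind(1:4, 2 * (1:4), -1 * (1:4))   # collinear points
  expect_error(superpose(line, line), "collinear")
})

test_that("structure model invariants are enforced", {
  at <- data.frame(chain = "A", resno = 1L, resid = "GLY", elety = "CA",
                   x = 0, y = 0, z = 0, het = FALSE)
  expect_error(structure_model(rbind(at, at)), "duplicate")
  at$x <- NaN
  expect_error(structure_model(at), "finite")
  expect_error(trajectory(toy_anchor_model(),
                          array(0, dim = c(1, 3, 3))), "topology error")
})
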