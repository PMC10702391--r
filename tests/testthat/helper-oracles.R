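# Independent brute-force oracles, deliberately written without reusing any
# package internals, plus small fixture builders.

oracle_rmsd <- function(a, b) {
  tot <- 0
  for (i in seq_len(nrow(a))) {
    tot <- tot + sum((a[i, ] - b[i, ])^2)
  }
  sqrt(tot / nrow(a))
}

oracle_dist <- function(p, q) sqrt(sum((p - q)^2))

# Minimal RMSD over all proper rotations + translations, by direct
# optimization over Euler angles from several starts (small systems only).
oracle_min_rmsd <- function(mobile, reference) {
  rot_from_angles <- function(ang) {
    ca <- cos(ang[1]); sa <- sin(ang[1])
    cb <- cos(ang[2]); sb <- sin(ang[2])
    cg <- cos(ang[3]); sg <- sin(ang[3])
    rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
    rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    rz1 %*% ry %*% rz2
  }
  mc <- sweep(mobile, 2, colMeans(mobile))
  rc <- sweep(reference, 2, colMeans(reference))
  obj <- function(ang) oracle_rmsd(mc %*% rot_from_angles(ang), rc)
  best <- Inf
  starts <- rbind(c(0, 0, 0), c(pi / 3, 1, -1), c(-1, 2, 0.5),
                  c(2, -0.7, 1.9), c(pi, pi / 2, -pi / 2), c(0.3, 2.8, 1.1))
  for (s in seq_len(nrow(starts))) {
    r <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    r <- stats::optim(r$par, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, r$value)
  }
  best
}

oracle_rmsf <- function(series_matrix) {
  # series_matrix: n_frames x 3 positions of one atom
  mu <- colMeans(series_matrix)
  sqrt(mean(rowSums(sweep(series_matrix, 2, mu)^2)))
}

random_rotation_matrix <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# Small single-chain model with the metric anchors at hand-picked
# coordinates; distances are trivially known.
toy_anchor_model <- function() {
  structure_model(data.frame(
    chain = "A",
    resno = c(366L, 442L, 400L, 487L, 396L, 601L, 602L, 603L, 700L, 700L),
    resid = c("SER", "GLY", "ASP", "ASP", "THR", "NA", "NA", "NA",
              "ASP", "ASP"),
    elety = c("CA", "CA", "CA", "CA", "CA", "NA", "NA", "NA", "CA", "CB"),
    x = c(0, 3, 6, 9, 12, 10, 7, 13, 2, 3),
    y = c(0, 4, 1, -2, 2, -1, 2, 3, 2, 3),
    z = c(0, 0, 2, 1, 0, 2, 3, 1, 1, 0),
    het = c(rep(FALSE, 5), rep(TRUE, 5))), label = "anchors")
}

# Trajectory with explicit per-frame coordinates supplied as a list of
# n_atoms x 3 matrices.
toy_trajectory <- function(model, frame_list, dt_ps = 500,
                           system_label = "WT", replicate_id = 1L) {
  fr <- array(0, dim = c(length(frame_list), nrow(model$atoms), 3L))
  for (i in seq_along(frame_list)) fr[i, , ] <- frame_list[[i]]
  trajectory(model, fr, dt_ps = dt_ps, replicate_id = replicate_id,
             system_label = system_label)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "eaatkit", mustWork = TRUE)
}
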