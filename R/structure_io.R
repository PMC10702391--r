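#' Construct a structure model
#'
#' A structure model is an ordered table of atoms with chain, residue and
#' atom identity plus Cartesian coordinates in Angstrom. Ions and ligands
#' read from HETATM records are first-class atoms distinguished by their
#' residue name and the `het` flag, so a sodium ion can be addressed by its
#' residue number exactly like a protein residue.
#'
#' @param atoms data.frame with columns `chain` (single character),
#'   `resno` (integer, PDB numbering), `resid` (residue name, up to three
#'   characters), `elety` (atom name, e.g. `"CA"`), `x`, `y`, `z`
#'   (Angstrom) and optionally `het` (logical, HETATM origin; default
#'   `FALSE`).
#' @param label free-text label carried along for reporting.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, label = "") {
  required <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("structure model must contain at least one atom")
  if (is.null(atoms$het)) atoms$het <- FALSE
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$resid <- as.character(atoms$resid)
  atoms$elety <- as.character(atoms$elety)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("atom coordinates must be finite")
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue_number, atom_name) identity: ",
         key[duplicated(key)][1L])
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, label = label), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %d atoms, chains %s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              nrow(x$atoms),
              paste(sort(unique(x$atoms$chain)), collapse = ",")))
  invisible(x)
}

#' Coordinates of a structure model as an n x 3 matrix
#' @param model a `structure_model`.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Construct a trajectory
#'
#' A trajectory is a frame-ordered set of coordinates sharing one topology
#' (a [structure_model]); every frame has exactly the topology's atoms.
#'
#' @param topology `structure_model` defining atom identities.
#' @param frames numeric array `n_frames x n_atoms x 3`, Angstrom.
#' @param dt_ps frame spacing in picoseconds (> 0).
#' @param replicate_id integer replicate label.
#' @param system_label system name, e.g. `"WT"` or a mutant.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(topology, frames, dt_ps = 500, replicate_id = 1L,
                       system_label = "WT") {
  stopifnot(inherits(topology, "structure_model"))
  if (length(dim(frames)) != 3L || dim(frames)[3] != 3L) {
    stop("frames must be an n_frames x n_atoms x 3 array")
  }
  if (dim(frames)[2] != nrow(topology$atoms)) {
    stop(sprintf("topology error: frames have %d atoms but topology has %d",
                 dim(frames)[2], nrow(topology$atoms)))
  }
  if (dim(frames)[1] < 1L) stop("trajectory needs at least one frame")
  if (!is.finite(dt_ps) || dt_ps <= 0) stop("dt_ps must be positive")
  structure(list(topology = topology, frames = frames, dt_ps = dt_ps,
                 replicate_id = as.integer(replicate_id),
                 system_label = system_label),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s replicate %d: %d frames x %d atoms, dt %g ps\n",
              x$system_label, x$replicate_id, dim(x$frames)[1],
              dim(x$frames)[2], x$dt_ps))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$frames)[1]

parse_pdb_lines <- function(lines, path = "<text>") {
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  idx <- which(is_atom)
  if (length(idx) == 0L) stop("no ATOM/HETATM records found in ", path)
  rec <- lines[idx]
  icode <- trimws(substr(rec, 27, 27))
  if (any(nzchar(icode))) {
    stop(sprintf("insertion codes are not supported (%s line %d)",
                 path, idx[which(nzchar(icode))[1L]]))
  }
  num_field <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(rec, from, to)))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      stop(sprintf("parse error: malformed %s field at %s line %d: '%s'",
                   what, path, idx[bad[1L]], lines[idx[bad[1L]]]))
    }
    v
  }
  data.frame(
    chain = substr(rec, 22, 22),
    resno = as.integer(num_field(23, 26, "residue number")),
    resid = trimws(substr(rec, 18, 20)),
    elety = trimws(substr(rec, 13, 16)),
    x = num_field(31, 38, "x coordinate"),
    y = num_field(39, 46, "y coordinate"),
    z = num_field(47, 54, "z coordinate"),
    het = startsWith(rec, "HETATM"),
    stringsAsFactors = FALSE
  )
}

#' Read a single-model PDB file
#'
#' Parses ATOM and HETATM records in file order. Files with insertion codes
#' or malformed coordinate fields are rejected with an error naming the
#' offending line. If the file contains several MODEL blocks only an error
#' is raised; use [read_multimodel_pdb()] for trajectories.
#'
#' @param path file path.
#' @param label optional model label (defaults to the file name).
#' @return a [structure_model].
#' @export
read_pdb <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (sum(startsWith(lines, "MODEL ")) > 1L) {
    stop("multi-model file; use read_multimodel_pdb(): ", path)
  }
  structure_model(parse_pdb_lines(lines, path), label = label)
}

#' Read a multi-model PDB file as a trajectory
#'
#' MODEL/ENDMDL records delimit frames; every model must contain the same
#' atoms in the same order, otherwise a topology error is raised. A file
#' without MODEL records is read as a single-frame trajectory.
#'
#' @param path file path.
#' @param dt_ps frame spacing in picoseconds.
#' @param replicate_id,system_label trajectory metadata.
#' @return a [trajectory].
#' @export
read_multimodel_pdb <- function(path, dt_ps = 500, replicate_id = 1L,
                                system_label = "WT") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- which(startsWith(lines, "MODEL "))
  if (length(starts) == 0L) {
    atoms <- parse_pdb_lines(lines, path)
    fr <- array(0, dim = c(1L, nrow(atoms), 3L))
    fr[1L, , ] <- as.matrix(atoms[, c("x", "y", "z")])
    return(trajectory(structure_model(atoms, label = basename(path)), fr,
                      dt_ps = dt_ps, replicate_id = replicate_id,
                      system_label = system_label))
  }
  ends <- which(startsWith(lines, "ENDMDL"))
  if (length(ends) != length(starts)) {
    stop("unbalanced MODEL/ENDMDL records in ", path)
  }
  models <- lapply(seq_along(starts), function(i) {
    parse_pdb_lines(lines[(starts[i] + 1L):(ends[i] - 1L)],
                    sprintf("%s (model %d)", path, i))
  })
  ref <- models[[1L]]
  key <- function(a) paste(a$chain, a$resno, a$elety)
  for (i in seq_along(models)) {
    if (nrow(models[[i]]) != nrow(ref) ||
        !identical(key(models[[i]]), key(ref))) {
      stop(sprintf("topology error: model %d of %s does not match model 1",
                   i, path))
    }
  }
  fr <- array(0, dim = c(length(models), nrow(ref), 3L))
  for (i in seq_along(models)) {
    fr[i, , ] <- as.matrix(models[[i]][, c("x", "y", "z")])
  }
  trajectory(structure_model(ref, label = basename(path)), fr,
             dt_ps = dt_ps, replicate_id = replicate_id,
             system_label = system_label)
}

format_pdb_records <- function(atoms, xyz) {
  # PDB atom-name column convention: names shorter than 4 start in column 14
  name <- ifelse(nchar(atoms$elety) >= 4L, substr(atoms$elety, 1, 4),
                 sprintf(" %-3s", atoms$elety))
  sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          ifelse(atoms$het, "HETATM", "ATOM"),
          seq_len(nrow(atoms)) %% 100000L, name, atoms$resid, atoms$chain,
          atoms$resno, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0)
}

#' Write a structure model or trajectory to PDB
#'
#' Trajectories are written as multi-model PDB (one MODEL block per frame).
#' Coordinates are written at the format's fixed precision (3 decimals), so
#' a write/read round trip preserves coordinates to 1e-3 Angstrom.
#'
#' @param x a [structure_model] or [trajectory].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "structure_model")) {
    out <- c(format_pdb_records(x$atoms, coords(x)), "END")
  } else if (inherits(x, "trajectory")) {
    nf <- n_frames(x)
    out <- unlist(lapply(seq_len(nf), function(i) {
      c(sprintf("MODEL %8d", i),
        format_pdb_records(x$topology$atoms, x$frames[i, , , drop = TRUE]),
        "ENDMDL")
    }))
    out <- c(out, "END")
  } else {
    stop("x must be a structure_model or trajectory")
  }
  writeLines(out, path)
  invisible(path)
}

#' Select a single atom from a structure model
#'
#' The selection is a partial function: it returns exactly one atom row or
#' raises a typed error. This is the primitive used to resolve metric
#' anchors such as the HP1/HP2 hairpin-tip C-alpha atoms or a sodium ion
#' addressed by residue number.
#'
#' @param model a [structure_model].
#' @param chain chain identifier, or `NA` to search all chains.
#' @param resno residue number.
#' @param elety atom name (e.g. `"CA"`); `NA` matches any atom name.
#' @return one-row data.frame (the atom) with an `index` column giving its
#'   position in the model.
#' @export
select_atom <- function(model, chain, resno, elety = "CA") {
  a <- model$atoms
  hit <- (is.na(chain) | a$chain == chain) & a$resno == resno &
    (is.na(elety) | a$elety == elety)
  q <- sprintf("(chain=%s, resno=%s, atom=%s)", chain, resno, elety)
  n <- sum(hit)
  if (n == 0L) stop("lookup error: no atom matching ", q)
  if (n > 1L) stop("integrity error: ", n, " atoms match ", q)
  out <- a[hit, , drop = FALSE]
  out$index <- which(hit)
  out
}

#' Indices of atoms matching a selector
#'
#' Vectorized companion of [select_atom()] used for ligand and fit-subset
#' selections. All non-`NULL` selector fields must match.
#'
#' @param model a [structure_model].
#' @param chain,resno,resid,elety,het selector fields; `NULL` means
#'   unconstrained. `resno` may be a vector.
#' @return integer vector of atom indices (possibly empty).
#' @export
atom_indices <- function(model, chain = NULL, resno = NULL, resid = NULL,
                         elety = NULL, het = NULL) {
  a <- model$atoms
  hit <- rep(TRUE, nrow(a))
  if (!is.null(chain)) hit <- hit & a$chain %in% chain
  if (!is.null(resno)) hit <- hit & a$resno %in% resno
  if (!is.null(resid)) hit <- hit & a$resid %in% resid
  if (!is.null(elety)) hit <- hit & a$elety %in% elety
  if (!is.null(het)) hit <- hit & a$het == het
  which(hit)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' `mobile[fit_idx, ]` and `reference[fit_idx, ]`, and applies the
#' transform to all rows of `mobile`. All fit atoms carry equal weight.
#' The returned rotation always has determinant +1 (no reflection).
#'
#' @param mobile,reference numeric n x 3 matrices with identical row
#'   correspondence.
#' @param fit_idx indices of the rows used to determine the transform
#'   (default: all rows). At least 3 non-collinear points are required.
#' @return list with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `fitted = mobile %*% rotation + translation`), `fitted`
#'   (transformed `mobile`) and `rmsd_fit` (post-fit RMSD over `fit_idx`).
#' @export
superpose <- function(mobile, reference, fit_idx = seq_len(nrow(mobile))) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference))) {
    stop("mobile and reference must have identical dimensions")
  }
  if (length(fit_idx) < 3L) {
    stop("degeneracy error: superposition needs at least 3 fit points")
  }
  m <- mobile[fit_idx, , drop = FALSE]
  r <- reference[fit_idx, , drop = FALSE]
  cm <- colMeans(m); cr <- colMeans(r)
  mc <- sweep(m, 2, cm); rc <- sweep(r, 2, cr)
  sv_m <- svd(mc)$d
  if (sv_m[2] <= 1e-8 * max(sv_m[1], 1e-12)) {
    stop("degeneracy error: fit points are collinear")
  }
  h <- crossprod(mc, rc)            # 3 x 3 covariance
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  trans <- cr - drop(cm %*% rot)
  fitted <- sweep(mobile %*% rot, 2, trans, "+")
  dev <- fitted[fit_idx, , drop = FALSE] - r
  list(rotation = rot, translation = trans, fitted = fitted,
       rmsd_fit = sqrt(mean(rowSums(dev^2))))
}

#' Root-mean-square deviation between two coordinate sets
#' @param a,b n x 3 matrices in row correspondence.
#' @return RMSD in the coordinate units (Angstrom throughout the package).
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  sqrt(mean(rowSums((a - b)^2)))
}
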