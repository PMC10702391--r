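#' Parse a somatic variant table
#'
#' Reads a CSV/TSV table with columns `gene`, `protein_change` (e.g.
#' `"R479W"`), `cancer_type` and `patient_id`, and decomposes each protein
#' change into reference residue, position and alternate residue. Rows
#' that cannot be parsed, or that are not missense (reference equals
#' alternate), are reported in an error table rather than silently
#' dropped.
#'
#' @param path file path, or a data.frame already in memory.
#' @param sep field separator; `NULL` (default) guesses from the file
#'   extension (`.tsv`/`.txt` tab, otherwise comma).
#' @return list with `records` (data.frame: gene, ref_aa, position,
#'   alt_aa, cancer_type, patient_id, source) and `errors` (data.frame:
#'   row, protein_change, reason).
#' @export
parse_variant_table <- function(path, sep = NULL) {
  if (is.data.frame(path)) {
    tab <- path
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(sep)) {
      sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
    }
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  }
  need <- c("gene", "protein_change", "cancer_type", "patient_id")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("variant table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(tab$source)) tab$source <- "unspecified"
  pc <- trimws(as.character(tab$protein_change))
  m <- regmatches(pc, regexec("^([A-Z])([0-9]+)([A-Z*])$", pc))
  ok <- lengths(m) == 4L
  ref <- ifelse(ok, vapply(m, function(g) if (length(g) == 4L) g[2] else NA_character_, ""), NA)
  pos <- ifelse(ok, vapply(m, function(g) if (length(g) == 4L) g[3] else NA_character_, ""), NA)
  alt <- ifelse(ok, vapply(m, function(g) if (length(g) == 4L) g[4] else NA_character_, ""), NA)
  reason <- rep(NA_character_, nrow(tab))
  reason[!ok] <- "unparseable protein_change"
  syn <- ok & ref == alt
  reason[syn] <- "synonymous (not missense)"
  nonsense <- ok & !syn & alt == "*"
  reason[nonsense] <- "nonsense (not missense)"
  keep <- ok & !syn & !nonsense
  records <- data.frame(
    gene = tab$gene[keep],
    ref_aa = ref[keep],
    position = as.integer(pos[keep]),
    alt_aa = alt[keep],
    cancer_type = tab$cancer_type[keep],
    patient_id = tab$patient_id[keep],
    source = tab$source[keep],
    stringsAsFactors = FALSE
  )
  if (any(records$position < 1L)) stop("variant positions must be >= 1")
  errors <- data.frame(row = which(!keep), protein_change = pc[!keep],
                       reason = reason[!keep], stringsAsFactors = FALSE)
  list(records = records, errors = errors)
}

#' Protein-change labels of variant records
#' @param records parsed variant records ([parse_variant_table()]).
#' @return character vector like `"R479W"`.
#' @export
protein_change <- function(records) {
  paste0(records$ref_aa, records$position, records$alt_aa)
}

#' Unique missense changes for a gene
#'
#' Uniqueness is by (reference residue, position, alternate residue);
#' the operation is idempotent and independent of record order.
#'
#' @param records parsed variant records.
#' @param gene gene symbol to restrict to; `NULL` keeps all records.
#' @return sorted character vector of unique protein changes.
#' @export
unique_missense <- function(records, gene = NULL) {
  if (!is.null(gene)) records <- records[records$gene %in% gene, , drop = FALSE]
  if (nrow(records) == 0L) return(character(0))
  ch <- protein_change(records)
  ord <- order(records$position, records$ref_aa, records$alt_aa)
  unique(ch[ord])
}

#' Mutation frequency as a percentage of patients
#'
#' `100 * n_mutations / n_patients`, the dataset-level comparison used to
#' contrast somatic and natural variation burden.
#'
#' @param n_mutations mutation count.
#' @param n_patients number of patients in the dataset (> 0).
#' @return percentage.
#' @export
frequency_percent <- function(n_mutations, n_patients) {
  if (!is.finite(n_patients) || n_patients <= 0) {
    stop("domain error: n_patients must be positive")
  }
  100 * n_mutations / n_patients
}

#' Classify variants by proximity to ligand binding sites
#'
#' A variant belongs to a site's proximity set iff the minimum distance
#' between any atom of its residue (all atoms, side chain and backbone)
#' and any atom of that site's ligand is less than or equal to `cutoff_A`
#' (boundary inclusive). Variants close to both ligands form the
#' `interface` set; positions absent from the structure are listed as
#' `unmapped` and excluded from all sets.
#'
#' @param model a [structure_model] containing the ligands.
#' @param changes character vector of protein changes (e.g. `"R479W"`) or
#'   parsed variant records.
#' @param orthosteric_ligand,allosteric_ligand selector lists passed to
#'   [atom_indices()], e.g. `list(resid = "ASP", het = TRUE)`.
#' @param cutoff_A distance cutoff in Angstrom (default 5).
#' @param chain chain used to map variant positions (default `"A"`).
#' @param offset added to variant positions to obtain structure residue
#'   numbers (default 0: sequence numbering coincides with the PDB).
#' @return object of class `proximity_sets`: list with `orthosteric`,
#'   `allosteric`, `interface`, `unmapped` (character vectors),
#'   `distances` (per-variant minimum distances) and `cutoff_A`.
#' @export
proximity_classify <- function(model, changes, orthosteric_ligand,
                               allosteric_ligand, cutoff_A = 5,
                               chain = "A", offset = 0L) {
  if (is.data.frame(changes)) changes <- protein_change(changes)
  changes <- unique(changes)
  o_idx <- do.call(atom_indices, c(list(model), orthosteric_ligand))
  a_idx <- do.call(atom_indices, c(list(model), allosteric_ligand))
  if (length(o_idx) == 0L) stop("orthosteric ligand selector matches no atoms")
  if (length(a_idx) == 0L) stop("allosteric ligand selector matches no atoms")
  xyz <- coords(model)
  min_dist <- function(idx_res, idx_lig) {
    d2 <- outer(rowSums(xyz[idx_res, , drop = FALSE]^2),
                rowSums(xyz[idx_lig, , drop = FALSE]^2), "+") -
      2 * xyz[idx_res, , drop = FALSE] %*% t(xyz[idx_lig, , drop = FALSE])
    sqrt(max(0, min(d2)))
  }
  pos <- as.integer(sub("^[A-Z]([0-9]+)[A-Z]$", "\\1", changes)) + offset
  d_orth <- d_allo <- rep(NA_real_, length(changes))
  mapped <- logical(length(changes))
  for (i in seq_along(changes)) {
    res_idx <- atom_indices(model, chain = chain, resno = pos[i], het = FALSE)
    if (length(res_idx) == 0L) next
    mapped[i] <- TRUE
    d_orth[i] <- min_dist(res_idx, o_idx)
    d_allo[i] <- min_dist(res_idx, a_idx)
  }
  in_orth <- mapped & d_orth <= cutoff_A
  in_allo <- mapped & d_allo <= cutoff_A
  structure(list(
    orthosteric = changes[in_orth],
    allosteric = changes[in_allo],
    interface = changes[in_orth & in_allo],
    unmapped = changes[!mapped],
    distances = data.frame(change = changes, position = pos,
                           mapped = mapped, d_orthosteric_A = d_orth,
                           d_allosteric_A = d_allo,
                           stringsAsFactors = FALSE),
    cutoff_A = cutoff_A
  ), class = "proximity_sets")
}

#' @export
print.proximity_sets <- function(x, ...) {
  cat(sprintf("<proximity_sets> cutoff %.1f A\n", x$cutoff_A))
  cat("  orthosteric:", paste(x$orthosteric, collapse = ", "), "\n")
  cat("  allosteric: ", paste(x$allosteric, collapse = ", "), "\n")
  cat("  interface:  ", paste(x$interface, collapse = ", "), "\n")
  if (length(x$unmapped)) {
    cat("  unmapped:   ", paste(x$unmapped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify a binding free-energy change
#'
#' Interprets a predicted change in binding free energy
#' (ddG = dG_bind(mutant) - dG_bind(WT), kcal/mol) with a symmetric
#' significance threshold: values above `+threshold` indicate a
#' significant *decrease* in binding affinity, values below `-threshold`
#' a significant *increase*, anything in between is nonsignificant.
#'
#' @param ddg_kcal_mol numeric vector of ddG values (kcal/mol).
#' @param threshold significance threshold in kcal/mol (default 1).
#' @return character vector: `"decrease"`, `"increase"` or
#'   `"nonsignificant"`.
#' @export
classify_ddg <- function(ddg_kcal_mol, threshold = 1) {
  if (any(!is.finite(ddg_kcal_mol))) {
    stop("domain error: ddG values must be finite")
  }
  ifelse(ddg_kcal_mol > threshold, "decrease",
         ifelse(ddg_kcal_mol < -threshold, "increase", "nonsignificant"))
}

#' Read a ddG table and classify each entry
#'
#' @param path CSV with columns `mutant`, `ligand`, `ddg_kcal_mol`, or a
#'   data.frame of the same shape.
#' @param threshold passed to [classify_ddg()].
#' @return the table with a `classification` column appended.
#' @export
read_ddg_table <- function(path, threshold = 1) {
  tab <- if (is.data.frame(path)) path else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("mutant", "ligand", "ddg_kcal_mol")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("ddG table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab$classification <- classify_ddg(tab$ddg_kcal_mol, threshold)
  tab
}
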