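#' Reference characterization values for EAAT1 variants
#'
#' Small plain-text tables shipped with the package summarizing the
#' published functional and computational characterization of EAAT1
#' (SLC1A3) disease-associated variants. They serve as default ground
#' truth for the synthetic generators and as worked-example inputs:
#'
#' * `"potencies"` — substrate potencies (pEC50) with maximal responses
#'   and inhibitory potencies (pIC50) of TFB-TBOA and UCPH-101 on
#'   wild-type and mutant cells, with `flag` marking not-determined and
#'   bell-shaped entries.
#' * `"ddg"` — predicted binding free-energy changes (kcal/mol) of
#'   mutants for the two substrates and two inhibitors.
#' * `"gate_openings"` — most frequent HP2-opening distance (mean +/- sd,
#'   Angstrom) of the representative frames per simulated system.
#'
#' @param which one of `"potencies"`, `"ddg"`, `"gate_openings"`.
#' @return data.frame.
#' @export
eaat1_reference <- function(which = c("potencies", "ddg", "gate_openings")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("eaat1_", which, ".csv"),
                      package = "eaatkit", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
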