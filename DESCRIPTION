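Package: eaatkit
Title: Structural Triage, Gating Metrics and Impedance Quantification for
    Glutamate Transporter Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize disease-associated variants of the
    glutamate transporter EAAT1 (SLC1A3) and related elevator-type
    transporters. Provides structure and multi-model trajectory input in
    PDB format with least-squares (Kabsch) superposition; variant table
    parsing with ligand-site proximity classification and binding
    free-energy change (ddG) interpretation; per-chain trajectory
    stability and gating metrics (RMSD, RMSF, hairpin-2 opening and
    sodium-site distances) with an instability exclusion rule, sampling
    density landscapes, and representative-frame selection for ensemble
    docking; quantification of impedance-based (RTCA) phenotypic assays
    from Cell Index through normalization, vehicle correction and net
    area-under-curve to variable-slope concentration-response fits with
    pathology flags, and Dunnett many-to-one comparisons. Synthetic-data
    generators with known ground truth make the full pipeline testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    multcomp,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
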