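---
title: "Methods: variant triage, gating metrics and impedance quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant triage, gating metrics and impedance quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eaatkit)
```

`eaatkit` characterizes missense variants of the glutamate transporter
EAAT1 (*SLC1A3*) along three axes: where a variant sits relative to the
ligand binding sites, how it changes the conformational dynamics of the
HP2 extracellular gate in molecular-dynamics (MD) trajectories, and how
it changes substrate and inhibitor potency in a label-free impedance
assay. This vignette documents the models, the tunable parameters, and
the design decisions behind each stage, and states what the synthetic
generators do and do not emulate.

## 1. Structural triage of variants

Variant tables (gene, protein change, cancer type, patient) are parsed
with strict missense semantics: synonymous and nonsense rows are
reported in an error table, never silently dropped, so cohort counts
remain auditable. Unique changes are defined by (reference residue,
position, alternate residue).

**Proximity classification.** A variant belongs to the orthosteric or
allosteric proximity set iff the minimum distance between *any* atom of
its residue (backbone and side chain) and *any* atom of the respective
ligand is at most the cutoff, 5 Å by default, boundary inclusive.
Membership in both sets defines the interface set. The published
practice in this field is visual inspection of a 5 Å shell; the
all-atom minimum-distance rule is this package's determinization of
that practice — it is reproducible, monotone in the cutoff, and
conservative (it never misses a contact visual inspection would count).
Variant positions are mapped on chain A by default with an optional
numbering offset; positions absent from the structure are reported as
unmapped rather than classified.

**ΔΔG interpretation.** Predicted binding free-energy changes
(ΔΔG~bind~ = ΔG~bind~(mutant) − ΔG~bind~(WT), kcal/mol) are *inputs*:
the energy function that produces them belongs to commercial modelling
suites and is out of scope. The package implements only the
interpretation layer, the symmetric ±1 kcal/mol significance rule
(> +1 ⇒ significant affinity decrease, < −1 ⇒ increase, otherwise
nonsignificant).

**A known discrepancy.** The cohort mutation frequency is computed as
100 × *n*~mutations~ / *n*~patients~. Published figures for the EAAT1
cancer cohort (1.18%) are not reproduced by this formula with the
printed unique-mutation count (105 / 10,179 × 100 = 1.03%); the
non-unique count that would reconcile them is not printed.
`frequency_percent()` implements the stated formula and the discrepancy
is documented here rather than resolved.

## 2. Trajectory gating metrics

Trajectories are multi-model PDB files sharing one topology. All
metrics are computed independently per chain — the three protomers of
the trimer operate independently, and published exclusion bookkeeping is
per (replicate, chain).

**Superposition.** Every frame is superposed onto frame 1 by the Kabsch
least-squares rigid-body fit (SVD of the 3 × 3 covariance, reflection
corrected, unit weights). The fit subset defaults to the protein Cα
atoms of the chain under analysis: the source protocol fits "to the
first frame" without naming the atom set, and per-chain fitting matches
the per-chain independence of every downstream metric. The rigid
transform is applied to all atoms of the frame so ions and ligands
follow their chain.

**Metrics.** Protein RMSD (chain Cα vs frame 1), ligand RMSD (heavy
atoms, measured in the protein frame of reference without re-fitting on
the ligand), per-residue Cα RMSF about the time-mean position, and four
anchored distances: HP2 opening (S366 Cα – G442 Cα, the hairpin tips)
and the three Na⁺-site distances (ion 601 – D487 Cα, ion 603 – T396 Cα,
ion 602 – D400 Cα). Residue anchors are configuration, defaulted to
EAAT1 numbering. Ions are resolved within the chain first; a monotopic
ion that carries no chain label is accepted by residue number across
the model.

**Instability exclusion.** A (replicate, chain) system is excluded when
its protein RMSD *reaches* 10 Å — implemented as max ≥ threshold at any
frame, which makes the boundary case 10.0 Å excluded and 9.9 Å kept,
and makes exclusion monotone in the threshold.

**Sampling density.** Pooled per-frame metrics of the non-excluded
systems are binned on a normalized 2-D histogram (default 60 × 60 over
the data range) whose mass integrates to one, with normalized 1-D
marginals. A histogram rather than a kernel estimator is the reference
implementation because the acceptance checks need exact normalization
and bin bookkeeping; a KDE would only smooth the same pool.

**Representative frames.** The "most frequent HP2 opening" is
determinized as: Freedman–Diaconis histogram over the pooled chain-A
values, mode = center of the highest bin, selection window = that bin;
`k = 5` frames are drawn uniformly (seeded) from the window, widening
once to the two adjacent bins if the modal bin holds fewer than `k`
frames. The published procedure names neither its mode estimator nor
its tolerance; this rule was chosen because it is reproducible and
parameter-light. Selected frames are exported as single-model PDBs
containing the chain-A protein atoms and the originally coordinated
Na⁺ ions, ready for ensemble docking (docking itself is out of scope).

## 3. Impedance assay quantification

The assay measures transporter-mediated cell swelling as impedance.
The pipeline is the composition

CI = (Z~i~ − Z₀)/15 Ω → nCI = CI/CI(t~ref~) → vehicle subtraction →
net AUC over [t~stim~, t~stim~ + 120 min] → % of reference →
variable-slope logistic fit,

with t~ref~ the stimulation time for substrate series and the
pretreatment time for inhibitor series. "Normalized to the time of"
is implemented as division (the RTCA convention); a subtraction variant
sits behind the `operator` switch since the source protocol does not
define the operator. Vehicle correction is pointwise on identical time
grids — a grid mismatch is an error, never silent interpolation. The
net AUC is a signed trapezoidal integral: negative excursions subtract.
Responses are expressed in percent of the plate's reference wells
(1 mM substrate on wild-type cells ≡ 100%).

**Concentration–response model.** A four-parameter logistic on log₁₀
concentration, `y = bottom + (top − bottom)/(1 + 10^((log10 XC50 − x)·hill))`,
fitted by Levenberg–Marquardt from a deterministic ladder of starting
points, Hill slope bounded |hill| ≤ 5 for stability. The bottom
asymptote is bounded below at zero by default: vehicle correction
defines the ligand-independent baseline as exactly zero, so a negative
plateau is unphysical, and without the constraint curves whose potency
lies near the top of the tested range leave the bottom unidentified and
the potency estimate unstable.

**Pathology flags** replace parameters instead of raising errors:

* `not_determined` — no concentration-dependent signal (observed
  per-concentration means span < 5% of reference), optimizer failure,
  fitted span < 5%, or fitted potency more than 0.5 log units outside
  the tested range. The 5% floor sits deliberately *below* the smallest
  maximal response at which potencies are still reported for these
  mutants (8% of reference); an earlier 10% draft floor would have
  flagged a determinate published row even on noiseless data. The
  0.5-log range margin keeps boundary estimation noise from discarding
  valid experiments while still flagging clearly extrapolated
  potencies.
* `bell_shaped` — stimulation curves that rise then fall (the published
  high-concentration L-aspartate behaviour of some HP2 mutants): the
  mean response of the three highest concentrations is below 70% of the
  maximum over the lower concentrations *and* the terminal slope over
  the last four concentrations is significantly negative (p < 0.05).
  The thresholds are this package's determinization of a narrative
  description; flagged fits report no potency or E~max~.

**Replication statistics.** The experiment is the replication unit:
parameters are summarized as mean ± SEM over per-experiment fits.
Many-to-one comparisons against the wild type use one-way ANOVA with
Dunnett's post hoc test (multivariate-*t* adjusted p-values, α = 0.05).
ELISA expression is summarized as fold over the non-induced wild-type
control, a ratio of means. The EC80 helper for protocol design uses
EC80 = EC50 · 4^(1/hill).

## 4. What the synthetic generators emulate

**Trajectories** (`gen_trajectory`). A deterministic toy protomer
(~56 Cα atoms spanning the anchor residues, three Na⁺ ions, an
aspartate ligand) is replicated into chains A–C. Per frame, the HP2 tip
is placed on a fixed axis at a distance drawn from the planted Gaussian
(mean/sd per system); global rigid tumbling (cumulative random rotation
and translation) is added and must be removed by the superposition
stage; small isotropic thermal jitter (0.03 Å) keeps the geometry
non-degenerate. Designated unstable (replicate, chain) systems receive
an alternating-sign internal deformation growing linearly to 12 Å —
past the 10 Å exclusion threshold by construction and immune to removal
by rigid-body fitting. The ligand either co-moves with its chain or
performs a Brownian walk; an optional ion-escape event moves one Na⁺
away from its site after a set frame. The generator emulates *the
statistical structure the metrics consume* — planted distributions,
instability, seeded reproducibility — and none of the physics: no
force field, no solvent, no realistic fold. Passing recovery tests
therefore validates the measurement pipeline, not any simulation
engine.

**Plates** (`gen_plate`). Well traces are built by inverting the Cell
Index formula around planted normalized-CI curves: a shared growth
curve, a vehicle drift added to every well (removed again by vehicle
correction), and a linear post-stimulation response ramp whose net AUC
encodes the planted response. The planted response per concentration
follows the 4PL (or a flat line, or a rise-then-fall bell built as
4PL × high-concentration decay). Noise is a 5% coefficient of variation
on each well's response amplitude plus a 0.5%-of-reference additive
floor and small trace noise — response noise in impedance assays scales
with signal, and a purely additive 5% noise would drown the low-E~max~
mutant rows (8–23% of reference) that the published table does
quantify. On a noiseless spec the pipeline recovers the planted nCI to
1e-12 and the planted potency to 1e-3: the generator is the exact
statistical inverse of the quantification stage.

One calibration deserves note: published potency tables normalized to
the 1 mM response (= 100%) sometimes print fitted E~max~ above 100%.
An ascending curve is self-consistent with both facts for exactly one
Hill slope — the one at which it passes through 100% at 1 mM.
`hill_for_reference()` solves for it and the generators use it for such
rows; rows with E~max~ ≤ 100 carry no constraint and default to
hill = 1.

**Variant tables** (`gen_variant_table`) plant one unique change per
position with Poisson-distributed recurrence, so unique counts and
frequencies have known truth.

All generator randomness flows from a single integer seed through a
local RNG stream; re-runs are bit-identical and never disturb the
caller's RNG state.

## 5. Problem sizes and numerical choices

The recovery studies run at the design of the emulated experiments:
plates with 2 duplicates × 3 experiments across half-log concentration
series (10 µM–1 mM substrates, 1 nM–10 µM inhibitors), and trajectory
studies with 10 replicates × 3 chains × 500 frames. The test suite uses
smaller trajectories (60–500 frames, 1–3 replicates) for unit-level
properties; oracle comparisons (brute-force superposition, closed-form
RMSF) run on ≤ 10-atom systems where exhaustive optimization is exact.
The Dunnett null-calibration check uses 1,500 simulated experiments,
which bounds the family-wise error estimate to about ±1.7% (3 binomial
sigma).

Numerical conventions: coordinates in Å with PDB fixed-width precision
(3 decimals) on output; 1-based PDB residue numbering; insertion codes
rejected; superposition requires ≥ 3 non-collinear fit points (second
singular value > 1e-8 × the first); time grids in minutes must match
exactly across wells; the 4PL is always fitted on log₁₀ molar
concentration.

## 6. Limitations

* The toy trajectory generator cannot expose force-field- or
  sampling-dependent behaviour; conclusions about real MD data are
  limited to the correctness of the measurement pipeline.
* Bell-shape and not-determined thresholds are determinizations of
  narrative criteria; different thresholds would move borderline calls.
* ΔΔG values are consumed, never computed; docking and pocket
  descriptors are out of scope.
* Trajectory input is multi-model PDB; binary MD formats would need an
  adapter behind the same `trajectory` contract.
* Variant positions are assumed to coincide with structure numbering
  unless an offset is supplied; no transcript-level mapping is done.
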