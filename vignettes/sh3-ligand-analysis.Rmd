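---
title: "Methods: SH3 lysine-anchored ligand analysis with sh3tools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SH3 lysine-anchored ligand analysis with sh3tools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sh3tools)
```

# The scientific problem

SH3 domains are ~60-residue interaction modules that bind proline-rich
ligands through two hydrophobic xP pockets and a charged specificity
pocket. The domain modelled by this package departs from the canonical
`PxxP`-reading mode in two ways: its second xP pocket carries an acidic
residue, which licenses a **centrally located lysine** at ligand position
+2, and its specificity pocket accepts **either arginine or leucine** at
position +5. Acidic residues N-terminal of the core (short distance
elements, SDEs) form additional salt bridges with a basic surface residue
near the first pocket. `sh3tools` provides a reusable, fully tested
implementation of the analyses used to characterize this recognition mode:
consensus-motif construction and scanning, ensemble interface bookkeeping,
per-residue interaction-energy decomposition, and binding-isotherm fitting
— together with seeded generators that replace the raw experimental data.

# Motif model

The ligand core is an eight-position window labelled −1…+6 relative to the
first conserved proline (position 0):

| position | −1 | 0 | +1 | +2 | +3 | +4 | +5 | +6 |
|---|---|---|---|---|---|---|---|---|
| allowed | A/P | P | any | K | P | any | L/R | L/P/S/T |

An optional *relaxed* pattern (`motif_pattern(relaxed = TRUE)`) also admits
arginine at +2 — an acceptable but weaker central anchor — and removes the
+6 constraint; it is off by default because the stringent pattern is the
high-affinity definition.

Scanning decisions:

* **Coordinates are 1-based inclusive** everywhere (R convention); the
  reported `start` addresses the −1 residue, so a match beginning at the
  fourth residue of a 12-mer has `start = 4`.
* **`X` (unknown residue) matches nothing**, at constrained and
  unconstrained positions alike. This is the conservative choice for
  proteome scanning: a window containing an unknown residue is never
  claimed as a hit.
* All overlapping matches are reported, sorted by start.

PFM columns are `(count + pseudocount) / (n + 20·pseudocount)` over the 20
standard residues; the default pseudocount 0.5 is the Jeffreys-like choice
that keeps log-odds scores finite without drowning a 14-sequence library.
Scores are `sum_p log2(p_p(w_p)/q(w_p))` in bits against a background `q`
(default uniform 1/20; a SwissProt-like composition ships as
`swissprot_background()`).

**Core anchoring.** Selection-pool 12-mers occasionally admit more than
one valid core. No anchoring rule for logo construction is given by the
experimental protocol, so the package makes its own choice
(`align_peptide_set`): a bootstrap PFM is built from the unambiguous
peptides, ambiguous peptides are anchored at their best-scoring core, and
ties break leftmost. This two-pass rule is deterministic and
order-independent.

# Proteome scanning

`scan_proteome` applies the same matcher across FASTA records
(line-wrapping and case insensitive), skipping records shorter than eight
residues with a warning and rejecting duplicate record identifiers
outright — silent last-wins behaviour would corrupt truth-table
evaluation. Each hit carries `flank_acidity`, the count of D/E in the up
to six residues N-terminal of the window, as a proxy for the acidic-SDE
enrichment seen in genuine partners. `rank_hits` orders candidates by a
weighted sum of log-odds score and flank acidity with deterministic
tie-breaking. No percent-similarity threshold is reimplemented from older
pattern servers; ranking is score-based.

# Ensemble interface analysis

Ensembles are multi-MODEL PDB files with an identical atom inventory per
model. Chimera constructs (domain fused to its own ligand through a
Gly/Ser linker) are handled by `strip_linker`, which removes the linker
residue range (e.g. 75–83) from every model before analysis.

Contact criteria default to standard geometric values, because the
interface server used in the original analysis does not publish its
internal rules exactly:

| criterion | default | note |
|---|---|---|
| H-bond donor–acceptor | ≤ 3.5 Å | D–H…A ≥ 120° applied only when explicit H present |
| salt bridge (Lys/Arg/His N⁺ to Asp/Glu O⁻) | ≤ 4.0 Å | termini not treated as charged |
| nonpolar C–C (apolar carbons) | ≤ 4.5 Å | carbonyl/carboxylate/amide/guanidinium C excluded |

Occupancy of a residue-pair interaction is the exact fraction of models in
which at least one atom pair of that kind satisfies the criterion. Band
labels follow the conventional ensemble language: conserved > 0.90 and
transient 0.21–0.50 are fixed by that convention; the 0.51–0.90
"moderate" band is this package's interpolation, and ≤ 0.20 is "weak".

`backbone_rmsd` superposes N/CA/C/O atoms by the Kabsch SVD solution
(reflections excluded) before computing the RMSD; it is symmetric and
invariant to rigid motions of either input to well below 1e-6 Å.
`relative_csp` combines amide shifts as `sqrt(dH² + (0.2·dN)²)` — the
field-standard ¹⁵N weight, as no combination formula is prescribed by the
source protocol — and divides by the standard deviation over residues, so
the relative CSP has unit SD by construction; identical inputs return
zeros with a `degenerate` flag rather than NaNs.

The default pocket map (`default_pocket_map()`) assigns receptor residues
to the four pockets of this interface in domain numbering: zero/upstream
pocket {25, 26}, first pocket {12, 56, 58, 59}, second pocket
{14, 17, 43}, third pocket {18, 20, 21}. It is data, not logic — any named
list of residue vectors works.

# Energy decomposition

`per_residue_decomposition` computes a single-trajectory interaction
energy `E(complex) − E(receptor) − E(ligand)` over four components and
attributes every cross term half to each partner residue, so residue
contributions sum to the component totals *exactly* (the conservation
tests assert 1e-6 kcal/mol):

* **Coulomb**: `332.0636 q_i q_j / (ε_int r)`, ε_int = 1.
* **Lennard-Jones 12-6**: Rmin/2 sums, geometric well depths; 1–4 pairs
  within a molecule scale by 1/1.2 (elec) and 1/2 (vdW) and are folded
  into the electrostatic and van der Waals components.
* **GB polar**: HCT pairwise-descreening effective Born radii (intrinsic
  radii minus a 0.09 Å offset, element-wise descreening scale factors),
  canonical GB cross term with Debye–Hückel screening
  `exp(−κ f_GB)` on the solvent part; κ from the ionic strength at 298 K
  (0.127 Å⁻¹ at the 150 mM default). Non-positive inverse radii are
  clamped with a warning.
* **SASA nonpolar**: Shrake–Rupley sphere sampling (960 points, probe
  1.4 Å), energy `0.0072·SASA + 0` kcal/mol.

This is a **functional-form reimplementation, not a force-field
reproduction**. The packaged parameter table
(`inst/extdata/minimal_params_*.tsv`) is a minimal heavy-atom amino-acid
set whose residue charges sum exactly to formal charges; it supports the
rank and conservation properties that are the acceptance surface.
Absolute agreement with published per-complex totals (tens of kcal/mol on
deposited NMR ensembles under a full force field) is explicitly out of
scope: it would require the deposited coordinates and the complete
parameter set. What the package asserts instead, and tests: pair-sum
equality with brute-force oracles, exact decomposition conservation, and
the rank property that the central +2 lysine is the largest attractive
ligand contribution on the planted salt-bridge fixture.

Protonation states are not assigned; hydrogens present in the input are
used as-is, and heavy-atom fixtures fall back to distance-only H-bond
criteria. How chimeric structures were fragmented into receptor + peptide
before the published energy analysis is not fully specified, so the
package takes an explicit ligand chain selection instead.

# Binding models

## ITC

The forward model is the standard perfusion-cell convention: after
injection *i* with cumulative volume `ΔV_i`,

```
Mt_i = M0 (1 − ΔV_i/2V0) / (1 + ΔV_i/2V0)
Xt_i = X0 (ΔV_i/V0) (1 − ΔV_i/2V0)
```

the 1:1 complex concentration solves the quadratic
`MX = [(nMt + Xt + Kd) − sqrt((nMt + Xt + Kd)² − 4 n Mt Xt)]/2`, and the
injection heat is `Q_i − Q_{i−1} + (dV/V0)(Q_i + Q_{i−1})/2` with
`Q = ΔH·MX·V0` (the half-plug term credits binding heat in the displaced
volume). The default schedule is 19 × 2 µl of 660 µM ligand into 200 µl of
60 µM protein. Enthalpy conservation (`ΣQ ≈ ΔH·n·M0·V0`) holds to < 1%
only when saturation occurs at small cumulative injected volume, so the
conservation test uses a rapidly saturating schedule; with the default
schedule the overflow loss is real, not a bug.

`fit_one_site` minimizes least squares over (log10 Kd, ΔH, N) with a
multistart over Kd decades (10⁻²–10³ µM), a Nelder–Mead polish, and a
Gauss–Newton covariance (`σ²(JᵀJ)⁻¹`, numerical Jacobian in natural
units). Flat heats or non-convergence yield a *flagged* fit, never an
exception, and low-c titrations are flagged informationally.

**Design deviation, and why.** The original plan modelled
control-titration subtraction as a free constant baseline in the fit.
Implementing that showed the free offset makes Kd practically
unidentifiable at c ≈ 1.3 (the weakest registry entry): the profiled
residual surface is flat in Kd far below the noise floor, and
inverse-variance pooling of such fits is badly biased. Since the bench
workflow subtracts the control heats *before* fitting — the data reaching
the fitter is already baseline-corrected — the package fits three
thermodynamic parameters by default and exposes the baseline as
`fit_baseline = TRUE` for uncorrected data.

Replicate pooling (`pool_kd`) is the maximum-likelihood estimator under
known per-replicate variances: inverse-variance weighted mean with pooled
variance `1/Σ(1/σ_i²)`, applied identically to Kd and stoichiometry;
non-finite-variance replicates are dropped with a warning.

## Dose–response

`fit_4pl` fits `y = bottom + (top − bottom)/(1 + (x/EC50)^hill)` in
log10(EC50) with a multistart over Hill slopes. Relative affinities use
the *fitted* half-saturation dose (reference/clone, reference ≡ 1) rather
than raw 50%-saturation interpolation, which is noise-fragile; this is a
documented divergence from the eyeball procedure it replaces. Fits whose
EC50 falls more than a decade outside the dosed range, or whose fitted
amplitude extrapolates the observed response range by more than 2×, are
flagged unidentifiable.

# The synthetic-data layer

Generators emulate every input class at the conditions the pipeline
expects, each deterministic under an explicit seed and RNG-state-local:

* `gen_peptide_library` — 12-mers with exactly one motif-conforming core
  (the selection-pool geometry), flanks from SwissProt-like composition.
* `gen_proteome` — 50 records of 150–400 residues by default, with
  planted cores and rejection of accidental background cores (the +2
  lysine of an accidental window is mutated away), so truth tables are
  exhaustive and recall/precision are exactly measurable.
* `gen_complex_ensemble` — Gaussian coordinate jitter (default 0.3 Å,
  a typical well-converged NMR-family spread) around `toy_complex()`, a
  hand-built schematic complex: a seven-residue receptor strand
  presenting Glu/Trp/Arg side chains opposite a PPPKPPRL ligand, with a
  planted salt bridge (ligand Lys4 NZ to receptor Glu2 OE1, 2.9 Å), a
  planted H-bond (receptor Arg6 NH1 to ligand Leu8 O, 3.0 Å) and
  nonpolar contacts from the two prolines flanking the tryptophan ring.
  Only interface distances are meaningful; no physical realism is claimed
  for the ensemble, and a green occupancy test establishes exact model
  counting, not conformational plausibility.
* `gen_titrations` / `gen_displacement_curves` — replicate sets around
  the fixture registries, with per-replicate derived seeds and truth
  serialized as JSON beside the TSVs.

**Fixture registries are the stated world.** `binding_truth_registry()`
carries the four measured dissociation constants (5.29, 15.70, 15.29,
46.65 µM) with equimolar stoichiometry; the binding enthalpies
(−8.6/−7.4/−7.9/−6.8 kcal/mol) are package choices in the typical
exothermic range for SH3–polyproline recognition, set once and not tuned.
`elisa_truth_registry()` carries the clone-1 EC50 of 363 nM with
plate-scale plateaus (top 1.2, bottom 0.05 absorbance units) and unit
Hill slope; doses emulate a 1–800 µg/ml competitor dilution converted at
34 kDa (a ~26 kDa GST tag plus the ~8 kDa domain). Default noise levels
are 0.1 µcal per injection (ITC) and 2% of top (plate reader).

# Numerical choices and degenerate inputs

* Optimizers: BFGS multistart + Nelder–Mead polish; relative tolerance
  1e-12/1e-14. Fit failures are flagged objects, not exceptions.
* PDB parsing keeps author numbering; alternate locations other than A
  are dropped; model-inventory mismatches are format errors naming the
  model.
* `relative_csp` requires ≥ 3 overlapping residues (an SD over fewer is
  meaningless) and flags the all-identical case.
* `strip_linker` with an empty range is the identity; stripping every
  atom is an error.
* Duplicate FASTA ids, ragged alignments, and non-amino-acid alphabets
  are rejected with specific messages.
* Seeds derived for replicates stay far below 2³¹.

# Known limitations

* The energetics module is a minimal GBSA machine for rank/conservation
  properties, not a calibrated affinity predictor: no entropy, no
  protonation, heavy-atom parameter set, schematic fixtures.
* Database-dependent published counts (e.g. how many family members carry
  an acidic second-pocket residue, out of how many sequences) are
  reproducible only against a specific alignment release; the MSA module
  exposes the generic column machinery and treats those counts as inputs,
  not acceptance values.
* Occupancy statistics are defined over this package's geometric
  criteria, which approximate but do not bit-reproduce any particular
  interface server.
* The one-site ITC model assumes a single class of equivalent sites;
  multi-site or cooperative schemes are out of scope.
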