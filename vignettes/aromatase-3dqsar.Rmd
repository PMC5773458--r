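---
title: "Interaction-feature 3D-QSAR of aromatase inhibition: methods and design notes"
author: "aromprofile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction-feature 3D-QSAR of aromatase inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aromprofile)
```

## The modelling problem

Aromatase (CYP19) converts androgens to estrogens; its inhibitors fall into
two mechanistic classes.  Type I steroidal inhibitors occupy the androgen
pocket, binding with their beta face toward the heme so that the C19 methyl
(or a 19-hydroxyl/19-keto oxygen) sits against the iron; Type II
azaheterocycles instead coordinate the heme iron through an aromatic ring
nitrogen.  `aromprofile` models the inhibition potency pIC50 of both classes
with a single interpretable linear model over a nine-entry interaction
fingerprint,

$$\mathrm{pIC_{50}} = \sum_i c_i\,\mathrm{FP}_i + C,$$

where FP1--FP7 are binary geometric interaction bits (six hydrogen bonds and
one heme--iron contact), FP8 is a continuous electronic coordination
descriptor, and FP9 is the hydrophobic-contact descriptor $\log P_C$.  Each
product $c_i\,\mathrm{FP}_i$ is the feature's independent contribution to
potency in log units, which is what makes the model a *profile* rather than
a black box.

## Geometric feature detection

A putative hydrogen bond (or heme interaction) is scored by the product of
three piecewise-linear block functions,

$$\Delta R = B(|d_{HA} - r|)\; B(|\alpha_{DHA} - \alpha|)\; B(|\beta_{HAX} - \beta|),$$

where $B(x, x_{ideal}, x_{max})$ is 1 inside the tolerance window, falls
linearly to 0 at the maximum deviation, and is 0 beyond.  Three parameter
presets govern the three interaction classes (ordinary hydrogen bonds, the
C19-oxygen--iron contact, and azaheterocycle--iron coordination); for the
heme interactions the iron is scored in the hydrogen role with the Cys437
thiolate as its donor.  A feature bit is set when $\Delta R \ge 0.6$
(boundary inclusive); the C19-carbon--iron interaction is a pure distance
rule, strict at 4.3 Å.

```{r presets}
block_params("hydrogen_bond")[c("r_ideal", "dr_ideal", "dr_max")]
delta_R(interaction_geometry(d_HA = 2.575, angle_DHA = 180, angle_HAX = 180))
```

Design points worth knowing:

* **Best-interaction convention.**  When several ligand atoms are eligible
  for one anchor the maximum $\Delta R$ wins, ties broken by lowest atom
  index: a feature is present if any atom realises it.  Distinct anchors are
  scored independently, so one hydroxyl can in principle set two bits; this
  matches the additive model.
* **Asp309 is treated as protonated** and therefore acts as the donor of
  FP2, pairing with a ligand acceptor.
* **Hydrogens.**  If a pose carries polar hydrogens they are used; otherwise
  idealised hydrogens are synthesised on hydroxyl oxygens and
  under-substituted nitrogens along the donor--acceptor line (making the
  donor angle ideal and leaving the distance term decisive).  Implicit
  placement is used only when no explicit donor hydrogen exists at all.
* **C19 identity is annotation, not perception.**  Steroid numbering cannot
  be derived from connectivity, so the C19 carbon/oxygen are per-ligand
  annotations, and the admissibility of the C19-oxygen substituent
  environment (R1/R2 hydrogens, R3 hydrogen or ketone) is likewise supplied
  as a boolean rather than perceived.
* Two candidate features (hydroxyl-O and nitro-O to Met374) are computed and
  reported but never enter the fingerprint: in the published model they were
  not selected, and we keep that structure.

## Bioactive-pose selection

Repeated docking produces a pose ensemble per ligand.  Poses are grouped by
greedy leader clustering in input order (the clustering algorithm itself is
a package decision; the contract is only the RMSD threshold), and only
conformations observed at least three times within 0.5 Å RMSD qualify as
candidates.  RMSD is computed over heavy atoms in the shared site frame
without superposition, which requires consistent atom ordering across poses.

Candidates are ranked by a score combining estimated potency with steric
hindrance $S = \sum U(r_{ij})$ over ligand--site atom pairs, where $U$ is a
12-6 Lennard-Jones potential on a compact element-level AMBER-style table
(Lorentz--Berthelot combination; the polar-hydrogen radius is 0.6 Å so
genuine hydrogen bonds do not register as clashes) and only remarkable
clashes with $U \ge 10$ kcal/mol are counted.  Two readings of the score are
implemented because the printed form ($\Delta G = \mathrm{pIC_{50}^{cal}} +
\log S$) rewards clashes if taken literally while the text calls $S$ a
hindrance: the default `penalty` mode subtracts $\log_{10} S$ (omitting the
term for $S < 1$), and a `literal` mode adds it.  Base 10 keeps the clash
term commensurate with pIC50.  Ties break by larger cluster multiplicity,
then input order; an empty candidate list returns an explicit
"no bioactive conformation" result.

## Hydrophobic contact ($\log P_C$, FP9)

The descriptor integrates a hydrophobicity density over the part of the
ligand's solvent-accessible surface in contact with the hydrophobic pocket
residues (Ile133, Phe134, Phe221, Trp224, Val370, Leu477 and neighbours).
The surface is sampled Shrake--Rupley style with a deterministic Fibonacci
lattice (probe 1.4 Å, ~4 points/Å$^2$), so each atom's point areas sum
exactly to its exposed accessible area.  The density model is a deliberate
surrogate: published per-atom logP-style increments spread uniformly over
each atom's exposed surface, conserving the atomic contribution exactly.
Any density model with per-atom conservation preserves the pipeline
structure — the QSAR coefficient rescales the descriptor — and the backend
is pluggable should a full solvation-free-energy-density field be wired in.
Negative (polar) contributions are integrated as-is, never clamped.

Contact is defined by a 4.5 Å cutoff from surface point to the nearest
hydrophobic pocket atom (a typical hydrophobic-contact distance; the cutoff,
grid density and probe radius are package decisions, configurable under
`logpc.*`).  Two exclusions apply, both because a transient contact does not
stabilise the complex: points inside the access-channel region (a convex
cylinder on the pocket flank near Phe221/Thr310), and atoms of flexible
substituents — operationalised as acyclic atoms whose chain back to the ring
system crosses at least two consecutive rotatable bonds, unless the branch
is pinned by a hydrogen bond or steric contact (`flag_flexible_atoms()`).

## The heme-coordination descriptor (FP8)

Binary presence/absence cannot carry a contribution that spans several log
units, so coordination strength is described electronically.  The condensed
dual descriptor $\Delta f(r) = f^+(r) - f^-(r)$ (positive: nucleophilic
site) is taken per atom from an external quantum-chemistry table — the
package performs no QM and is agnostic to the condensation scheme — and the
*smallest* dual descriptor over the azaheterocycle ring atoms,
$\Delta f(r)^S$, is the working descriptor.  Its calibration pathway is the
indirect one: the coordination contribution of a ligand is estimated by
subtracting the steroid-model-explained contributions from the experimental
potency (`coordination_residual()`), and an ordinary least-squares line of
those residuals on $\Delta f(r)^S$ (`fit_descriptor_line()`) yields the
transform

$$\mathrm{FP8} = 38.587\,\Delta f(r)^S + 3.931$$

applied only to ligands whose coordination geometry bit (azaheterocycle
preset) is set; FP8 then enters the generalized model with coefficient 1.
Whether the published constants came from this regression or from a joint
refit is not stated in the source; the package reproduces the regression
pathway.

## Weighted GA-MLR

The design table is fit by exact weighted least squares (QR-solved normal
equations) with per-class weights — steroids 1.0, azaheterocycles 0.1,
reflecting the weaker structural evidence for the azole binding mode.  The
weights apply to fitting and to the leave-one-out refits; per-class
validation metrics are reported unweighted.  LOO $Q^2$ uses the exact
hat-matrix identity $e_{(-i)} = e_i/(1 - h_{ii})$, with the explicit-refit
route retained as an oracle.  $R^2$ is reported both as squared Pearson
correlation (the common QSAR convention) and as the coefficient of
determination, since conventions differ.

Feature selection is a seeded binary-mask genetic algorithm (population 50,
100 generations, uniform crossover, mutation 0.02, elitism 2, all
configurable).  The fitness is the leave-one-out $Q^2$ minus a small
parsimony penalty (0.002 per selected feature, configurable).  The penalty
is deliberate: a pure-$Q^2$ objective retains a noise feature whenever its
spurious t-statistic exceeds roughly 1, which happens for a substantial
fraction of datasets at any sample size, so subset selection on raw $Q^2$
alone cannot reliably discard null candidates; the penalty makes a feature
earn its place while leaving genuinely informative features (whose $Q^2$
gain is an order of magnitude larger) untouched.  Setting `parsimony = 0`
restores the raw objective.

## What the synthetic generator emulates — and what it does not

Every fixture in the package is generated in code: a schematic binding site
in a canonical frame (iron at the origin, heme nitrogens at ±2 Å on the
axes, thiolate on the −z axis, hydrogen-bond anchors 6.4--7.2 Å above the
heme plane pointing at the pocket centre), poses whose groups are placed
inside, at, or outside the block-function windows, jittered ensembles with
displaced decoys, and fingerprint/activity cohorts drawn from the
generalized model.

The cohort defaults are chosen once to emulate the study conditions the
model was built for, and the reasoning is recorded here because several
numbers interlock:

* **Sizes** 122 steroids + 87 azaheterocycles (the training split of the
  209-compound set).
* **Descriptor ranges.**  $\log P_C$ is uniform over the published
  class ranges (steroids 1.286--2.125, azoles 0.203--1.910).
  $\Delta f(r)^S$ is drawn as $-0.065 + 0.15\,\mathrm{Beta}(2,5)$: through
  the FP8 transform this spans roughly 1.4--7.2 log units of coordination
  contribution, and the right skew encodes that only a few azoles are
  letrozole-class coordinators while most coordinate weakly.
* **Coordination misfit.**  The electronic descriptor explains only part of
  the coordination contribution, so cohort activities include a Gaussian
  misfit term (SD 0.74 log units) on coordinated ligands.  With the
  descriptor variance implied by the Beta draw (~0.86), this sets the
  descriptor-vs-contribution correlation at $R^2 \approx 0.61$ — the same
  number the calibration-line recovery test checks at $n = 87$.
* **Noise and feature prevalences** (defaults FP1 0.15, FP2 0.35, FP3 0.25,
  FP4 0.60, FP5 0.35, FP6 0.05, FP7 0.60, noise SD 0.3) were set by analytic
  variance bookkeeping so that a paper-noise-scale cohort (pooled MAE ≈
  0.45, i.e. noise SD ≈ 0.56) yields a weighted training $R^2$ near 0.73
  with $Q^2$ a few hundredths below — the performance regime of the real
  training set.  FP6 is rare because an azole nitrogen that coordinates the
  iron is rarely simultaneously hydrogen-bonded to Met374.

What passing tests on this generator shows: the detector reproduces
controlled geometry exactly; the estimator recovers known coefficients; the
validation machinery lands in the intended performance regime under
realistic signal-to-noise.  What it does not show: anything about real
molecules.  The synthetic "ligands" are minimal atom clouds with valid
elements and bonds, not chemistry; conformational strain, tautomers,
protonation, docking errors and dataset curation noise are all outside the
generator's world, and the published compound set itself is not
redistributed here.  Results on synthetic cohorts bracket the published
statistics distributionally; they do not reproduce the exact values, whose
train/test split is unpublished.

## Numerical choices and degenerate inputs

* Block functions are exact piecewise-linear comparisons; the 0.6 bit
  threshold is inclusive and the 4.3 Å carbon rule strict, as printed.
* $S = 0$ (no clash) makes $\log S$ undefined; the clash term is omitted.
* Greedy leader clustering is deterministic in input order; empty inputs
  give empty outputs, and a ligand with no candidate clusters yields an
  explicit no-conformation result rather than an error.
* Rank-deficient designs are rejected naming the collinear columns; a
  constant descriptor makes the calibration line unfit table stakes and is
  an error.
* Buried atoms have zero exposed area and contribute nothing to
  $\log P_C$; excluding every atom gives exactly 0.
* All generators and the GA take explicit seeds and restore the caller's
  RNG state.

## Problem sizes used by the test-suite simulations

Unit and acceptance tests run at the scale of the study itself: cohorts of
200--209 compounds, 20-seed recovery batches, 87-point calibration lines,
1000-point block-function grids, and pose ensembles of ~10 members.  These
sizes keep every statistical check well-conditioned while the whole suite
completes in well under a minute of compute.

## Known limitations

* The hydrophobicity density is a per-atom surrogate, not a solvation
  free-energy field; absolute $\log P_C$ values are only meaningful up to
  the rescaling absorbed by the FP9 coefficient.
* Element-level Lennard-Jones parameters are adequate in the $U \ge 10$
  clash regime they are used in, but are not a force field.
* Fukui values are inputs; enthalpy/HOMO-LUMO columns are passed through
  for reporting only.
* Pharmacophore refinement (adjusting the geometric windows) is exposed as
  "edit the config and re-run", not as an automated optimiser.
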