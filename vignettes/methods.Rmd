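---
title: "Models and numerical methods in hydrobind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in hydrobind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hydrobind` estimates receptor–ligand binding thermodynamics from
simulation snapshots and characterizes the thermodynamics of interfacial
water. This vignette records the models, the tunable parameters, and the
numerical decisions, so that every number the package produces can be
traced to an explicit choice.

## The MM-PBSA model

The binding free energy is assembled per snapshot as

$$\Delta G = \underbrace{E_{vdw} + E_{elec} + \Delta E_{deformation}
  + \Delta G_{PB} + \Delta G_{SA}}_{\Delta H} + (-T\Delta S).$$

Assumptions inherited from this family of methods: snapshots are drawn
from equilibrated ensembles; explicit waters are stripped before every
term and their effect enters only through the continuum terms; the
receptor's internal energy is never differenced (its two large absolute
internal energies would contribute noise far larger than the binding
signal), so only the *ligand* deformation penalty appears; and entropy is
estimated separately (quasiharmonic for the ligand, hydration-site terms
for the solvent) rather than from the same ensemble average.

Key parameters and defaults:

* **Coulomb constant** 332.0637 kcal·Å/(mol·e²) — the CHARMM convention;
  all charges are in elementary charge units, distances in Å.
* **Solute–solute dielectric** 2.0 for the interaction and deformation
  electrostatics, reflecting electronic screening in the protein
  interior. The water environment energy (explicit solvent) uses 1.0.
  Both are arguments, not constants.
* **No nonbonded cutoff** in any MM-PBSA term: the systems are finite
  snapshot ensembles and the post-hoc energies are cheap, so exactness is
  preferred over the truncation conventions that differ between MD codes.
  The only cutoff in the package is inside the Monte Carlo water sampler.
* **1–4 scaling** for intra-ligand nonbonded pairs defaults to 1.0 (full
  interaction) and is exposed as `scale14`; bonded (1–2) and 1–3 pairs are
  always excluded. Different force-field families make different choices
  here, and the convention used by any given parameter set is the user's
  to declare.
* **Block standard errors**: a series is split into 20 equal contiguous
  blocks (remainder truncated) and the SEM is the standard deviation of
  block means over $\sqrt{20}$. Differences of means (the deformation
  penalty) propagate the two SEMs in quadrature.
* **Snapshot stride**: `floor(duration / stride)` snapshots; a 10 ns
  trajectory at a 10 ps stride yields 1000.

### Per-residue decomposition

Interaction terms are attributed to the ligand atom's group — one group
per residue sidechain plus a single pooled mainchain group, because
mainchain contributions at a peptide interface are a property of the
backbone as a whole rather than of an individual position. Intramolecular
(deformation) pair energies crossing two groups are split half-and-half
between the partners, and torsions follow their central bond (halved when
the central bond itself crosses groups). The per-group PB desolvation is
computed with *all other ligand atoms deleted* while the receptor and the
grid geometry stay fixed; identical grids keep lattice noise out of the
differences. Because continuum electrostatics is not additive, the sum of
per-residue PB terms is *not* constrained to match the whole-ligand PB
term, and the package reports both without reconciling them. The
per-residue SASA term omits the 0.92 kcal/mol intercept, which belongs to
the binding event, not to a residue. The percent column is each group's
share of the grand total of the per-group sums, so it adds to 100 by
construction.

## The Poisson–Boltzmann solver

`pb_solvation()` solves the linearized PB equation on a cubic
finite-difference grid with successive over-relaxation (SOR, relaxation
parameter 1.9, relative residual tolerance $10^{-6}$; non-convergence is
an error, never a silent return). Nonlinear PB is out of scope: the
linearized form is the standard mode of the established solvers this
implementation follows.

* **Dielectric boundary.** The molecular (solvent-excluded) surface is
  realised as a signed level field on the grid: a point is interior when
  its distance to the solvent-accessible complement is at least the probe
  radius (1.4 Å). The level combines an analytic per-atom depth — exact
  for convex patches, which keeps the Born-ion benchmark clean — with an
  exact lattice Euclidean distance transform that seals reentrant volume
  between atoms (grid morphological closing). A node-offset margin of
  $\sqrt{3}h/2$ is subtracted from the lattice distance so the closing
  never overreaches; the cost is that reentrant sealing is conservative
  by up to one grid cell.
* **Link dielectrics.** Grid-link permittivities are harmonic averages
  weighted by the linear-interpolation crossing fraction of the level
  field, which restores sub-grid boundary placement. This is what brings
  the Born ion within 3% at 0.35 Å spacing despite the lattice.
* **Focusing.** Three levels by default: the coarsest box spans the
  solute plus a 20 Å margin with analytic Debye–Hückel boundary
  potentials; each finer level takes boundary values interpolated from
  the previous solution. The finest grid always keeps the entire solute
  (plus 2 Å) inside, so no charge is ever off-grid; the target fine
  spacing (0.5 Å default) is honoured only when that constraint allows.
* **Reaction-field energy.** The grid self-energy is cancelled by a
  matched second solve with homogeneous dielectric $\varepsilon_{in}$ and
  zero salt on identical grids:
  $G = \tfrac12\sum_i q_i(\phi_{solv}(r_i) - \phi_{hom}(r_i))$. Note this
  definition deliberately includes the change in Coulomb screening of
  *intra-solute* interactions — for two unit charges 60 Å apart it differs
  from the sum of two isolated solvation energies by exactly
  $q_1 q_2 (1/\varepsilon_{out} - 1/\varepsilon_{in})\,332.0637/r$, and
  the test suite asserts that identity rather than naive additivity.
  Binding calculations need this: the desolvation term must capture how
  complexation re-screens the partners' interactions.
* **Salt.** $\kappa^2 = 4\pi l_B \sum_i n_i z_i^2$ for a 1:1 salt at the
  stated ionic strength (0.145 M default) and 300 K, zeroed inside the
  solute and within the 2.0 Å Stern layer of any atom surface.
* **Charges.** PARSE-style charges and radii feed the PB path; the MM
  charge set is carried separately on the same atoms so the two never mix.

The SASA term uses Shrake–Rupley with a 960-point Fibonacci sphere per
atom (quadrature error below 0.5% on a lone atom) and the linear model
$0.00542 \cdot \Delta SASA + 0.92$ kcal/mol.

## Entropy estimators

**Quasiharmonic (ligand).** Frames are superposed onto their iteratively
refined mean structure by a mass-weighted Kabsch fit, which projects out
overall translation and rotation. The mass-weighted covariance of the
remaining fluctuations is diagonalized; the six smallest-eigenvalue modes
are discarded *by rank* (deterministic, unlike a magnitude threshold);
each retained mode contributes the quantum harmonic-oscillator entropy at
298 K with $\omega_i = \sqrt{k_B T/\lambda_i}$. Degenerate inputs are
handled explicitly: a rigid-body trajectory yields zero entropy, and any
near-null modes beyond the expected six raise a rank-deficiency warning.
At least $3N$ frames are recommended (a warning below that), and the
suite checks that halving the frame count moves the result by under 2%.

**Hydration sites (first-order inhomogeneous solvation theory).** The
excess entropy of a site splits into a translational term
$-k_B\langle\ln(\rho_{site}/\rho_{bulk})\rangle$ and an orientational term
$-k_B\langle\ln g_{or}\rangle$, both estimated with nearest-neighbour
(Kozachenko–Leonenko) estimators rather than histograms — unbiased at the
sample counts a 2000-snapshot analysis actually provides. The
orientational estimator works on the rotation manifold with the geodesic
rotation-angle metric, folds distances by the water $C_2$ symmetry
(symmetry number 2), and normalizes against the symmetry-reduced uniform
distribution, so uniform orientations give zero. Fully frozen
orientations would send the estimator to infinity; the geodesic radius is
floored at $10^{-4}$ rad and a saturation warning emitted. Only
first-order terms are implemented; site–site correlations and
higher-order terms are out of scope. The translational/orientational
split is reported explicitly because the first-order expansion fixes only
their sum's form, not the bookkeeping.

Temperatures follow the stage that uses them: quasiharmonic entropy at
298 K, hydration-site terms at 300 K; both are arguments.

## Hydration-site workflow

Clustering is greedy density clustering of pooled water-oxygen positions:
the sample with the most neighbours within the 1.0 Å site radius becomes
a centre, samples within the 2.4 Å exclusion radius are removed, and the
loop stops when the best remaining count drops below 25% of the frame
count. The three radii/thresholds are conventional values for
water-site mapping and are exposed as arguments. Ties are broken by
lexicographically smallest position so the result is independent of
sample order. Occupancy counts *frames with at least one water* (the
nearest is characterized when several co-occupy), keeping occupancies in
[0, 1]; occupancy weighting multiplies enthalpy, entropy, and free energy
alike, and `dG = dH + (-TdS)` holds exactly at every level of
aggregation.

Apo-versus-bound comparison classifies each apo site: *displaced* when a
bound-ligand heavy atom lies within 2.0 Å and no bound site matches
within 1.5 Å — the water returns to bulk, so binding gains the negated
apo excess values; *stabilized* when a bound site matches — binding gains
the bound-minus-apo difference; *unchanged* otherwise. Ambiguous
multi-matches resolve to the nearest site, with a message.

The bulk reference (the zero of all site enthalpies) is the mean
environment interaction energy of a bulk water, computed from the
package's own sampler (below) or any user-supplied bulk trajectory; an
inner-radius inclusion rule supports droplet-style input where surface
waters must be trimmed.

## Synthetic data: what it emulates and what it does not

`gen_water_box()` replaces bulk-water MD with Metropolis Monte Carlo of
rigid 3-site waters (TIP3P parameters) in a periodic cube sized from the
target density: the observable of interest — the mean configurational
interaction energy of a water with its environment — depends only on the
equilibrium configuration distribution, which MC samples directly. A
periodic box replaces a bounded droplet deliberately: it removes the
surface layer that droplet simulations must trim away. Moves are
single-molecule translations (±0.15 Å) and rotations about the oxygen
(±0.3 rad), tuned for ~40–45% acceptance; the sampling cutoff is 8.5 Å
with molecule-based minimum image (dipoles never split), with no
long-range correction. Snapshots are separated by at least 5N attempted
and N accepted moves. The suite verifies detailed balance in expectation
by Boltzmann-reweighting an 8-water box across temperatures. Under these
conditions the 216-water box at 0.997 g/cm³ and 300 K yields a bulk
environment energy near −19.6 kcal/mol — about 1 kcal/mol more negative
than droplet-based estimates, a known sensitivity of this observable to
boundary treatment and truncation that sits within the tolerance the
package's acceptance check uses. What the sampler does *not* emulate:
polarization, bond flexibility, long-range (Ewald) electrostatics, and
dynamics of any kind (no time correlation functions can be read off these
snapshots).

`gen_tethered_waters()` provides the estimator oracle: oxygens drawn from
an isotropic Gaussian (closed-form translational excess entropy), and
orientations either uniform or concentrated with rotation-angle density
$\propto (1-\cos\omega)e^{\kappa\cos\omega}$, whose exact
symmetry-folded excess entropy is evaluated by deterministic 2-D
quadrature and returned as ground truth. Unoccupied frames park the water
far away, so the trajectory keeps a fixed atom count while occupancy
measurements see true absences.

`gen_toy_complex()` exercises the whole MM-PBSA path at desk scale with
every force-field constant recorded, so brute-force double loops can
re-derive every energy; its unbound pose differs by a sidechain torsion
swing, giving a small, non-zero deformation penalty. It is a test
instrument, not a model of any real complex — passing on it demonstrates
bookkeeping correctness, not force-field realism.

## Numerical choices and degenerate inputs

* Indexing is 1-based everywhere inside the package (the R convention);
  PDB serials stay 1-based on I/O, so round trips are lossless.
* Alternate locations keep the highest-occupancy conformer; insertion
  codes are part of the residue key.
* Water detection is a residue-name whitelist (`HOH`, `WAT`, `TIP3`,
  `TIP4`, `SPC`, `SOL`), overridable per call.
* Atom pairs closer than $10^{-4}$ Å raise a near-singularity error
  naming the pair; colinear torsion geometries raise a geometry error;
  zero-radius atoms are excluded from SASA with a warning; a site with
  zero occupancy has undefined thermodynamics and errors rather than
  returning NaNs.
* The mainchain atom set is {N, CA, C, O, terminal OXT/OT1/OT2, and
  hydrogens bonded to these (bond table when present, name conventions
  otherwise)}; the sidechain is the residue complement, so the two
  partition each residue exactly. This partition is a documented package
  decision — decomposition conventions differ between codes and no single
  standard exists.
* Hydrogen bonds default to donor–acceptor distance ≤ 3.5 Å and
  D–H–A angle ≥ 120°; crystal structures without hydrogens use the
  heavy-atom-only mode (distance test only, recorded on the result). A
  bridging water with several partners on one side still counts once.
  Census counts are monotone non-increasing as criteria tighten, and the reference
  interface counts this census is designed to reproduce are
  criteria-sensitive — the defaults are a documented choice, not a
  derivation.

## Problem sizes

The shipped tests and the acceptance script run at sizes chosen for a
single CPU: the water box at 216 waters with 200 snapshots (the study
condition for the bulk reference), tethered-site recovery at 2000 frames,
quasiharmonic recovery at 10⁴ frames over 3 atoms, PB benchmarks on
49³–97³ grids with focusing to ≤ 0.35 Å where the Born comparison needs
it, and toy complexes of 2–3 ligand residues with 6–8 frames when PB and
SASA run per frame. All of these scale up unchanged — grid dimension 129
and thousand-snapshot strides are arguments, not limits.

## Known limitations

* The PB solver is a lattice method: energies carry a grid bias that the
  focusing schedule and harmonic link dielectrics reduce but do not
  eliminate; comparisons between states should always share grid
  geometry (the pipeline does this automatically).
* First-order solvation entropy only; correlated waters and evacuated
  (dewetted) cavities are outside the model.
* The quasiharmonic model assumes one dominant conformational basin;
  multi-basin ligands will be over-stabilized.
* The MC water model is rigid TIP3P with truncated electrostatics — the
  bulk reference it produces is internally consistent for site ΔH values
  computed with the same conventions, but it is not an Ewald-quality
  absolute number.
* mmCIF input, topology auto-generation, and protonation assignment are
  not implemented; inputs are expected to arrive prepared.
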