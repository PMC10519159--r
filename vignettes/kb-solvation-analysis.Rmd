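---
title: "Methods: Kirkwood-Buff analysis of opposing cosolvent effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Kirkwood-Buff analysis of opposing cosolvent effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbsolv)
```

## The model

kbsolv analyses a two-state conformational equilibrium of a protein in a
binary water (1) / cosolvent (3) mixture: a folded helix dimer (h)
against two isolated unfolded coils (c). The thermodynamic driver of a
cosolvent's effect on this equilibrium is the excess preferential
solvation

$$\Delta\Gamma_{23} \;=\; \Gamma_{23}^h - \Gamma_{23}^c, \qquad
  \Gamma_{23}^\alpha = \rho_3\,(G_{23}^\alpha - G_{21}^\alpha),$$

with the Kirkwood-Buff integrals computed as truncated running
integrals of site-averaged radial distribution functions,

$$G_{ij}^\alpha(R) = M_\alpha \int_0^R \left(g_{ij}^\alpha(r) - 1\right)
  4\pi r^2\, dr ,$$

where the multiplicity $M_\alpha$ is 1 for the dimer and 2 for the coil
(the unfolded reference is *two* monomers, so every per-monomer coil
integral and excluded volume is doubled before comparison). The excess
decomposes exactly into a cosolvent term $\rho_3(G_{23}^h - G_{23}^c)$
and a water term $\rho_3(G_{21}^c - G_{21}^h)$; both identities are
enforced to $10^{-12}$ in `delta_gamma()` and surfaced end to end by the
pipeline.

The linkage to the experimental m-value of the linear stability model
$\Delta G_{helix}(c) = \Delta G_0 - m\,c$ runs through the bulk
concentration-fluctuation factor $a_{33} = 1/(1 + \rho_3(G_{33} -
G_{31}))$:

$$m = \frac{\Delta\Gamma_{23}\, a_{33}}{\beta\,\rho_3},
  \qquad \beta = 1/(RT)\ \text{in mol/kcal}.$$

**Where the a33 factor sits is a genuine design decision.** Printed
renderings of this linkage are typographically ambiguous between
$\Delta\Gamma_{23} = m\beta\rho_3/a_{33}$ and $\Delta\Gamma_{23} =
m\beta\rho_3 a_{33}$. We adopt the first form, for two reasons that
must hold simultaneously: (i) an $a_{33}$ below 1 signals cosolvent
clustering and must *amplify* the excess solvation at fixed m, and
(ii) only this form makes a modest helix-inducing m-value of 0.15
kcal mol⁻¹ M⁻¹ project to an excess solvation of order 10 at 7 M when
$a_{33}$ dips to ~0.16–0.18 — the self-consistency check encoded in
`test-thermo.R` ("small a33 amplifies"). The rejected form would
*suppress* the excess in exactly the regime where clustering matters.

## Units

One canonical unit set is used everywhere to avoid silent factor
errors: lengths in nm, energies in kcal/mol, charges in e,
concentrations in mol/L, number densities in nm⁻³ (1 M =
0.6022140857 nm⁻³). The Coulomb prefactor is 33.20637 kcal nm mol⁻¹
e⁻², the gas constant 1.987204×10⁻³ kcal mol⁻¹ K⁻¹, so
β(300 K) = 1.6774 mol/kcal. PDB coordinates (Å) are converted on read;
GRO files are native nm. Orthorhombic boxes only — triclinic input is
rejected rather than silently mishandled.

## Estimator conventions

**RDF weighting.** $g_{ij}$ is the *pair-count-weighted* site-averaged
RDF: all A–B atom-pair minimum-image distances are histogrammed and each
bin is normalized by $n_A\,\rho_B\,V_{shell}$ with $\rho_B$ the bulk
*atom* density of set B. Whether a site-averaged RDF should weight
site pairs by pair count or uniformly is underdetermined in common
usage; pair-count weighting is the convention that matches
normalization by an atom number density (the two coincide for
equal-size sites). Downstream, KB integrals are multiplied by the
*molecule* number density ρ3, pairing an all-atom-averaged g with a
per-molecule density.

**Bulk density.** By default $\rho_B$ is the in-box atom count over the
box volume. For prescribed-profile synthetic data the generator's known
bulk density should be passed explicitly (`bulk_density=`): the in-box
count includes the local excess/depletion around the solute, which
would bias the recovered g by a factor $1 + G/V$ — a bias of order 1 nm³
on the KB integral at desk-scale box volumes, larger than the counting
noise.

**Truncation and plateau.** $G(R)$ uses midpoint-rule quadrature on the
histogram grid (default bin 0.002 nm, so quadrature error is far below
sampling error; desk-scale sampled tests use 0.02 nm). The long-range
limit is the mean of $G(R)$ over a trailing window (default: final 10%
of the R range); beyond an optional trust radius $G$ is extended as a
constant — the constant-extrapolation rule for coil integrals judged
converged at a smaller radius than the half-box. A convergence
diagnostic (max |dG/dR| over the window, threshold 0.05 nm³/nm) flags
drifting tails without suppressing the result; the threshold is a
package choice since "well converged" has no universal criterion. No
finite-size KB corrections are applied: plain truncation plus constant
extrapolation is the convention this analysis chain is built around.

**Errors.** All error bars are standard deviations over five contiguous
equal trajectory blocks (n−1 denominator), reported as sd of block
means, not sem. Γ and ΔΓ uncertainties are obtained by recomputing the
full g → G → plateau → Γ chain per block, which preserves the strong
covariance between $G_{23}$ and $G_{21}$ that linear error propagation
would drop. Five blocks make the sd itself noisy (χ² with 4 df); the
test suite therefore uses exact Poisson counting SEs where a single KB
integral is compared against a closed form, and block SEs for compound
quantities.

## The synthetic-data generator

The generator replaces microsecond-scale explicit-solvent ensembles
with configurations whose statistics are prescribed, so every estimator
has an oracle:

* **Prescribed-profile mode** places solvent molecule centres around a
  point reference with one-particle density exactly
  $\rho\,g_{target}(r)$ for a piecewise-constant target, uniform beyond
  the last breakpoint, in spherical or cylindrical geometry. The KB
  integral of the target has a closed form stored in the ground truth
  (`analytic_G`, checked against quadrature to $10^{-10}$). The
  per-frame molecule count is fixed at the total intensity so all
  frames share one topology; shell counts are multinomial with the
  exact Poisson means (dispersion within 0.1% of Poisson at the
  occupancies used — the chi-square property test treats them as
  Poisson). Profiles reaching beyond the half-box are rejected because
  truncated KB integrals would be silently biased.
* **Oriented mode** adds a two-site tail–head cosolvent whose
  tail-to-head vector is drawn from a per-shell law over cosθ against
  the outward direction — a point mass, or any bounded density on
  [−1, 1] (rejection sampling; normalization validated numerically).
  An inward bias (cosθ → −1) in the solvation shell emulates the
  reverse-micelle-like arrangement in which cosolvent head groups face
  the protein.
* **Monte Carlo mode** (`mc_sample()`) is a single-particle Metropolis
  sampler with LJ + cutoff-Coulomb interactions around a rigid solute —
  the interacting-fluid companion used for sign tests on data with real
  excluded volume and attraction. It is deliberately minimal: point
  solvent, translation moves, tuned step size; a statistical stand-in,
  not an MD engine.

**What the defaults emulate, and what they do not.** The preset study
conditions mirror a coiled coil in a cosolvent/water box at mole
fraction 0.04: water at 33.2 molecules/nm³, cosolvent at 1.38 nm⁻³
(≈2.3 M), 6 nm cubic box, 120 frames — chosen once as the realistic
desk-scale transcription of those conditions. The `tfe_like` preset
gives the helix dimer a much stronger cosolvent shell than the coil
(side-chain-affine helix inducer); `urea_like` reverses the imbalance
toward the doubled coil (backbone-affine denaturant); both give the two
coils a larger water hard core than the dimer, so the water term is
negative in either case. Passing tests on these data validate the
estimators — normalization, truncation, multiplicity, decomposition,
error blocks — not the physics of any real cosolvent: the generator has
no solvent–solvent structure (irrelevant to one-particle KB estimators
but real in MD), no conformational fluctuations of the solute, and
prescribed rather than emergent orientation.

**Solute geometry.** The toy dimer is two parallel straight bead
strands (rise 0.15 nm/residue, inter-axis spacing 1.0 nm) with
side-chain beads pointing away from the interface — capturing the one
geometric fact the analysis depends on: side chains exposed, backbone
buried. The coil is a fixed-step (0.38 nm) self-avoiding walk with
exposed backbone. A dimer needs ≳12 residues before its long axis
dominates the principal-component variance; axis-based analyses on
shorter toys will lock onto the inter-strand direction instead.

## Geometry analyses

The helix axis is the principal direction of the main-chain atoms
through their centroid (sign: positive dot with +z, ties toward +x) —
one of several reasonable definitions, so it is recorded in output
metadata. Cylindrical distributions count target atoms whose axial
coordinate falls inside the instantaneous main-chain extent (slab
restriction; the alternative fixed-length slab changes only the
normalization constant). Orientation histograms bin each cosolvent
molecule by its *tail* atom distance and normalize to unit integral
over cosθ per distance bin; the reverse-micelle detector is a one-sided
z-test (α = 0.01, ≥50 molecules per shell) on mean cosθ < 0.

## Excluded volume and the water term

$V_{21}$ is the volume impenetrable to the centre of a water-sized
probe (radius 0.14 nm): the union of spheres of radius
$r_{atom} + r_{probe}$, counted on a regular grid (default 0.02 nm,
guard: spacing ≤ probe/2; halving the spacing moves fixture volumes by
<0.5%). Atom radii default to the LJ minimum half-distance
$\sigma 2^{1/6}/2$, overridable — published analyses rarely state their
radius set. Interior cavities larger than the probe are *not*
subtracted; grid/probe free-volume estimators share this convention and
the cavity contribution is of order 0.1% for compact helical proteins,
so correcting would break parity with the quantity being emulated.
$V_{21}$ is averaged over frames (for a flexible solute a
representative-structure value is a different, less robust choice).
In the hard-core limit $G_{21} = -V_{21}$ exactly, which the tests use
to tie the KB water term to $-\rho_3(V_{21}^c - V_{21}^h)$; with
attractive protein–water interactions $|G_{21}| < V_{21}$ and the
comparison (`compare_water_term()`) is interpretive, not pass/fail.

## Energy decomposition

Protein–cosolvent energies are summed over minimum-image pairs within a
1.0 nm real-space cutoff — no Ewald, no shifting, no tail corrections.
That is a deliberate parity choice: the decomposition targets
near-surface interactions, and a truncated sum is the form whose
main-chain/side-chain × Coulomb/LJ split is exactly additive (both
identities hold to machine precision by construction). Lorentz–
Berthelot combining is the default (arithmetic σ, geometric ε, the
Amber-family convention); geometric σ is available. Energies are totals
per simulation cell, not per molecule. Intra-molecular exclusions never
arise because only inter-molecular protein–cosolvent pairs are summed.
Atoms closer than 10⁻⁴ nm abort the sum (overlap catastrophe rather
than a silently huge term).

## Role classification

Backbone atoms default to {N, CA, C, O, OXT, H, H1–H3, HA, HA1–HA3} —
a convention, not a structural fact, hence a configurable default with
a strict mode that errors on unmapped names. Glycine's HA2/HA3 are
backbone. `main_chain ∪ side_chain` always partitions the protein
atoms; all non-protein atoms are `solvent`.

## Problem sizes and determinism

The shipped tests and the acceptance script run on 5–6 nm boxes,
100–200 frames, and solvent counts of a few hundred to ~7,500 atoms —
sizes chosen so the full suite completes in well under a minute of
compute while keeping counting SEs small against the effect sizes
(e.g. the preset ΔΓ23 magnitudes of ~4–5 against block SEs of ~1).
Every stochastic routine takes an explicit seed (fixture default
20231001); identical seeds give bit-identical trajectories and
byte-identical pipeline outputs, which the tests assert.

## Known limitations

* No finite-size or closure corrections to KB integrals; the truncation
  conventions are those of the analysis being reproduced, not the
  state of the art in KB estimation.
* The MC mode is not thermostatted dynamics: no water model, no
  multi-site solvent, no barostat. It exists for qualitative sign
  oracles only.
* File support covers PDB, GRO and the internal columnar format;
  binary trajectory formats (XTC/TRR) are out of scope — convert
  upstream.
* The pipeline's files mode estimates bulk densities from in-box
  counts, which carries the $1 + G/V$ bias discussed above; for small
  boxes supply densities explicitly.
* `a33` tables are linearly interpolated and never extrapolated;
  concentrations outside the table are an error, and the pure-water
  limit a33(0) = 1 is hard-coded.
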