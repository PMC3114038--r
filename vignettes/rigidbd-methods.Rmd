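---
title: "Models and methods behind rigidbd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rigidbd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rigidbd` simulates solutions of many rigid proteins with implicit-solvent
Brownian dynamics and analyses their oligomerization and adsorption on a
hydrophobic surface. This vignette is the package's own account of the
model: the energy function and its parameters, the propagation algorithm,
the analyses, the synthetic test species, and the numerical and design
choices made where the design was genuinely open.

## The interaction model

Each species is a rigid body: an atom table (positions in the body frame,
centered on the geometric center; radii; partial charges; per-atom solvent
accessible surface area computed in the unbound body) plus a reduced set of
effective charge sites. Four scalar fields are mapped onto regular grids in
the body frame of each species:

* **Φ_el** — electrostatic potential, kcal/mol/e. The built-in generator is
  a Debye–Hückel screened-Coulomb superposition over the effective charge
  sites, `Φ(r) = Σ_j q_j C e^{-κd_j} / (ε_s d_j)` with `C = 332.0636`
  kcal·Å/mol/e²; an externally solved linearized Poisson–Boltzmann map can
  be imported in OpenDX format instead and is used verbatim. The screening
  parameter κ follows from the ionic strength and temperature
  (κ⁻¹ ≈ 13.6 Å at 50 mM, 300 K).
* **Φ_ed** — electrostatic desolvation, kcal/mol/e², acting on the squared
  charges of the partner:
  `Φ_ed(r) = α C (ε_s−ε_p)/(ε_s(2ε_s+ε_p)) Σ_i a_i³ e^{-2κd_i}/d_i⁴`,
  clamped inside atoms (`d_i < a_i` → `a_i`), α = 1.67. This penalizes
  bringing a charge next to a low-dielectric volume.
* **Φ_np** — non-polar (hydrophobic) desolvation, kcal/mol/Ų. A partner
  atom of area A at position r contributes `β·A·b(r)`, with burial fraction
  `b = 1` inside the solvent-excluded region, decaying linearly to 0 over a
  ramp beyond the closest atom surface. β < 0 makes burial favourable
  (−0.018 kcal/mol/Ų in solution runs, −0.013 with the surface present).
* **E_sc** — soft-core repulsion, kcal/mol:
  `E_sc(r) = γ Σ_i a_i^n / (|r−r_i|^n + σ^n)`, finite at atom centers,
  smoothness set by σ (3.0 Å in solution, 1.5 Å in surface runs), decay by
  `n = 6`, magnitude by γ.

The pair interaction free energy sums, over both directions between bodies
1 and 2, `½ Φ_el·q + Φ_ed·q² + Φ_np·A + E_sc`, with the electrostatic
fields evaluated at the partner's effective charge sites and the
desolvation/soft-core fields at all partner atoms, each after transforming
the partner sites into the grid owner's body frame (minimum-image
displacement between centers under periodic boundaries). The
protein–surface energy keeps only the non-polar and soft-core terms — the
graphite slab is uncharged and fully hydrophobic — with the slab's
electrostatic desolvation field available as an option.

Grid convention: "size L at spacing h" means `round(L/h)+1` nodes per axis
with inclusive endpoints, centered on the body origin. Defaults mirror the
published setup (electrostatic and non-polar grids 80 Å at 1.0 Å,
soft-core 60 Å at 1.0 Å; surface fields 0.5 Å). The graphite fields are
built on a single rectangular unit-cell tile (2.46 × 4.26 Å) and evaluated
with periodic wrapping in x,y, which is exact for the infinite slab and
keeps the grids small; per-axis spacing is used there so the cell is a
whole number of nodes.

## Propagation

Positions and orientations follow the overdamped (Ermak–McCammon) update:
`Δr = (D_t Δt / k_BT) F + R` with `⟨R⟩ = 0`, `⟨R²⟩ = 6 D_t Δt` isotropic
(hydrodynamic interactions neglected), and the analogous body-frame
rotation with `D_r` and the torque, composed onto a unit quaternion that is
renormalized each step. The timestep is 0.5 ps, temperature 300 K,
snapshots (poses and the recomputed total energy) every 0.5 ns by default.
Periodic boundaries in x,y (and z in solution runs); with the surface, the
slab sits at the bottom and the top is specular-reflective. Random numbers
come from R's generator in a fixed per-body order, so a run is bit
reproducible given its seed.

Forces and torques in the engine are the *analytic gradients of the
trilinearly interpolated energy* — the h → 0 limit of the central finite
differences used by the `force_torque()` contract (h_t = 0.5 Å,
h_r = 0.02 rad defaults). Within a grid cell the interpolant is smooth, so
the gradient is exact for the energy actually being sampled; the test suite
verifies the two routes agree and that the gradient matches infinitesimal
finite differences of the pair energy to 10⁻⁴. This choice removes a
~12-fold cost over naive finite differencing without changing the sampled
distribution.

Validation of the propagation (all in the test suite and the acceptance
script): the fitted MSD slope of a free body recovers `6 D_t` to ~1%;
the body-axis autocorrelation decays as `exp(−2 D_r t)`; a body in an
external harmonic well (a validation-only potential) samples the Boltzmann
variance `k_BT/k`; recorded snapshot energies equal an offline
recomputation over unique pairs plus surface terms.

## Analyses

An *encounter complex* between two bodies exists when at least `N_ind`
independent atomic contacts occur: atom pairs (one atom from each body)
closer than `d_c`, such that the selected atoms within each body are
pairwise farther than `d_min` apart. The contact count is computed as the
exact maximum number of mutually independent contacts by branch-and-bound
over the candidate cross pairs. The number of candidate pairs at a real
interface is small, so the exact search is cheap; beyond a node budget the
deterministic greedy ascending-distance selection (a lower bound) is used
instead. The greedy rule can be suboptimal when an accepted short pair
blocks two compatible longer pairs, which is why the exact count is the
normative one; the test suite checks it against exhaustive subset
enumeration on hundreds of random instances.

Oligomers are the connected components of the encounter graph
(`N_ind = 2`, `d_c = 4.5` Å, `d_min = 6.0` Å for atomic-resolution models;
protein–surface contacts use `d_c = 4.0` Å). Oligomer fractions χ_n are
time averages over the production segment (the first 10% of each run is
discarded as equilibration; the radial distribution function of consecutive
trajectory thirds provides the convergence check). Tetramers are classified
by composition (AAAA / ABAB with two of each / BBBB / other), harvested at
1 ns intervals, superposed by least-squares (Kabsch) fitting on a reference
chain, and clustered with the GROMOS-style algorithm: the structure with
the most neighbours within the RMSD cutoff (15 Å) seeds a cluster, its
members are removed, repeat; ties break to the lowest structure index, and
the RMSD is computed over all atoms of the complete oligomer. Atomic
contact probabilities are `p_i = n_i / max_j n_j`; a residue is flagged
relevant when any of its atoms exceeds the third quartile of the per-atom
distribution, zeros included (the most conservative reading). Density
profiles are normalized by the bulk density — the upper half of the box by
default — so a uniform region reads 1.

## The synthetic species

`make_toy_protein()` builds an amphipathic rigid body at the hydrophobin
scale: `n = 64` beads of radius 3 Å quasi-uniformly on a 15 Å sphere
(Fibonacci lattice), a contiguous hydrophobic cap holding 27% of the beads
(patch area 750 Ų split evenly over the cap), Stokes–Einstein diffusion
constants (1 cP, 300 K: D_t = 14.6 Ų/ns, D_r = 4.9·10⁻² rad²/ns — within
15% of the tabulated hydrophobin values), molecular mass 7.5 kDa for
concentration/box conversions, and a net-neutral charge arrangement:
dipolar (±2 e at ±0.35 R on the patch axis) or quadrupolar (four
alternating ±2 e sites in four sectors around the patch axis at the patch
rim; zero dipole).

Three design decisions deserve emphasis, all fixed from direct inspection
of pair potentials of mean force and of literature-scale oligomer rates
*before* the qualitative acceptance comparisons were run:

1. **The hydrophobic face is flat** (`flat_patch = TRUE`): cap beads are
   projected onto the plane through the cap boundary. A purely spherical
   cap makes point contact only — measured patch–patch binding collapses to
   about −1 k_BT with no detectable independent contacts, and adsorption to
   −2 k_BT — so neither oligomerization nor surface accumulation can occur.
   Surface-active amphipathic proteins expose a flat hydrophobic face; with
   it, the face–face well is −9 k_BT with 4–6 independent contacts, and
   flat-on-surface adsorption is −6 k_BT.
2. **Polar beads carry 30% of the patch bead area**
   (`polar_sasa_fraction = 0.3`). The parent all-atom energy converts the
   buried area of *every* atom via β; with strictly zero polar weight,
   face-to-face dimers are absorbing end states and tetramers never occur
   (zero in 12 μs of sampling, versus the scaled literature expectation of
   ~0.003–0.06 per frame at 16 bodies). The 0.3 weight restores weak
   non-specific burial attraction: at 20 g/L the pure-dipolar system shows
   χ₁ ≈ 0.77, χ₂ ≈ 0.20 and a 4-mer rate inside the expected band, while
   2 g/L stays essentially monomeric — the concentration dependence the
   solution study reports.
3. **Coarse-grained interaction widths**: the soft-core magnitude is
   rescaled to γ = 24 kcal/mol (the published 64 kcal/mol is calibrated for
   all-atom site densities; summing 1/d⁶ tails over a whole bead shell at
   γ = 64 leaves no bound state), and the non-polar burial ramp is 10 Å —
   the scale of the hydrophobic attraction range — rather than one water
   diameter. The slab's own burial field uses a 14 Å ramp because the dense
   graphite soft-core holds beads at a 7–8 Å stand-off; a bead at stand-off
   is then about half buried. Protein–protein fields are identical between
   solution and surface regimes apart from the published β and σ changes,
   which keeps solution-phase behaviour consistent across regimes.

For trajectory analyses of these bead models the contact criterion is
scaled with the bead/atom size ratio: `d_c = 10` Å, `d_min = 12` Å
(`d_c = 9` Å against the surface). The atomic values remain the package
defaults.

What the toy species do *not* emulate: sequence-level detail, specific
residue chemistry, disulfide-constrained loops and their conformational
change, crystal-packing contacts, and shape anisotropy beyond the flat
face. Passing the scaled-down analogues therefore demonstrates that the
machinery — fields, propagation, criterion, analyses — reproduces the
qualitative physics (concentration-dependent oligomerization, suppression
by a quadrupolar conformer, hydrophobically driven surface accumulation),
not that the toy is a quantitative model of any real protein.

## Scaled-down study conditions

Full-scale simulations of this kind (512 proteins, 10 μs) are not reproducible at
desk scale; the acceptance analogues use 16 bodies and microsecond runs:

* **Concentration scan**: 16 dipolar bodies at 2, 5, 10 and 20 g/L, three
  seeds, 1 μs each (0.5 ps steps, snapshots every 0.5 ns, first 100 ns
  discarded). The fraction of molecules in trimers and larger must not
  decrease with concentration (within twice the pooled seed standard
  error).
* **Mixture comparison**: pure dipolar versus 50/50 dipolar/quadrupolar at
  20 g/L, three seeds, 1 μs per run.
* **Adsorption profile**: 16 bodies at 20 g/L over a 200 × 200 Å HOPG slab
  (box height from the equivalent cubic volume ≈ 249 Å), 1 μs; the profile
  peak must sit within 1.5 body radii of the surface and exceed twice the
  bulk density.

## Numerical choices and limitations

* Trilinear interpolation is exact at nodes and for multilinear fields;
  off-node it resolves the bound-state pair energetics to better than 2%
  under grid halving at the production spacings (0.75 Å non-polar and
  soft-core, 1.0 Å electrostatic for the toys). The steep repulsive wall
  converges more slowly (~5–10%), which is acceptable because the wall only
  needs to repel. The RMS relative error of off-node soft-core
  interpolation at 1.0 Å spacing is about 5%, concentrated where the field
  curves fastest; the field values mapped onto the nodes themselves are
  exact to machine precision.
* The engine skips the force loop for pairs beyond `force_range`
  (default in the pipelines: 42 Å, where the toy pair energy is below
  0.1 kcal/mol); recorded energies always use the full grid range.
* The screened-Coulomb fallback clamps distances below 1 Å when
  superposing site potentials; imported Poisson–Boltzmann grids bypass it.
* Degenerate inputs: empty PQR files, malformed records (reported with
  line numbers), zero-charge species (electrostatic terms vanish exactly),
  boxes smaller than twice the body diameter (minimum image invalid,
  refused), over-dense random packing (bounded rejection sampling, then an
  error), and empty production segments (analysis refuses rather than
  returning empty tables).
* Known limitations: no hydrodynamic coupling (deliberate, following the
  parent method), rigid bodies only, no image-charge treatment of the
  slab, single-stream RNG (no parallel propagation), and O(N²) neighbour
  search per step — adequate for tens of bodies, not thousands.
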