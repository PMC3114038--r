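# rigidbd

Rigid-body Brownian dynamics of many-protein solutions and their adsorption
on hydrophobic surfaces, in R with a compiled propagation core.

Small surface-active proteins such as class II hydrophobins diffuse in
solution as a concentration-dependent mixture of monomers and oligomers, and
accumulate against hydrophobic substrates through a solvent-exposed
hydrophobic patch. `rigidbd` implements the simulation machinery needed to
study this behaviour at atomic detail with implicit solvent:

- **Interaction energies on grids.** For each rigid species the four
  interaction fields are precomputed on regular 3-D grids: the screened
  electrostatic potential Φ_el (Debye–Hückel superposition over effective
  charge sites, or an imported Poisson–Boltzmann map in OpenDX format), the
  electrostatic desolvation field Φ_ed acting on squared partner charges,
  the non-polar desolvation field Φ_np (β × burial fraction, rewarding
  burial of solvent-accessible area), and the soft-core repulsion
  E_sc(r) = γ Σ_i a_i^n / (|r−r_i|^n + σ^n). The pairwise interaction free
  energy ΔG sums, over both directions, ½ Φ_el q + Φ_ed q² + Φ_np A + E_sc
  evaluated by trilinear interpolation at the partner's sites.
- **Ermak–McCammon propagation.** N rigid bodies move by
  Δr = (D_t Δt / k_BT) F + R with ⟨R²⟩ = 6 D_t Δt, and rotate analogously
  with D_r and the torque, composed onto a unit quaternion. Forces are the
  exact gradients of the interpolated energies. Periodic boundaries, with an
  optional graphite (HOPG) slab at the bottom of the box and a reflective
  top.
- **Analyses.** Encounter complexes via the independent-atomic-contact
  criterion (≥ N_ind contacts closer than d_c, mutually independent beyond
  d_min), oligomer fractions χ_n, tetramer composition classes
  (AAAA/ABAB/BBBB), GROMOS-style conformational clustering of harvested
  oligomers after least-squares superposition, per-atom contact
  probabilities with third-quartile residue selection, center–center g(r)
  and surface-normal density profiles normalized by bulk density.
- **Synthetic species.** A generator of amphipathic toy proteins (bead
  shells with a flat hydrophobic face and dipolar or quadrupolar charge
  arrangements) so the whole pipeline runs without external structures or
  solvers.

## Worked example

```r
library(rigidbd)

# an amphipathic toy protein with a flat hydrophobic patch and its grids
toy <- make_toy_protein("toyA", charge_pattern = "dipolar")
toy <- prepare_toy_species(toy)
toy
#> rigid-body species 'toyA': 64 atoms, 64 residues, net charge +0.000 e
#>   Rg 14.30 A | bounding radius 18.50 A | D_t 14.6 A^2/ns | D_r 0.0488 rad^2/ns
#>   2 effective charge sites | grids: el,ed,np,sc

# 16 copies at 20 g/L, 50 ns of Brownian dynamics at 300 K
p <- sim_params(t_total = 50, box = box_from_concentration(7.5, 16, 20),
                species_counts = c(toyA = 16), t_equil = 5, seed = 11)
traj <- run_simulation(list(toy), p, force_range = 42)
traj
#> BD trajectory: 16 bodies, 101 frames (50 ns, cadence 0.5 ns)

# time-averaged oligomer fractions under the bead-scale contact criterion
oligomer_fractions(traj, list(toy), toy_contact_criterion())[1:3, ]
#>   n        chi
#> 1 1 0.61675824
#> 2 2 0.35851648
#> 3 3 0.02472527
```

Over this short 50 ns window at 20 g/L roughly a third of the molecules
sit in dimers at any instant, with a small trimer population (longer runs
relax towards about a fifth in dimers) — the concentration-dependent
monomer/oligomer equilibrium the solution study targets. A surface run adds
`surface = surface_grid_set(build_hopg_layer(200, 200, 3), toy_energy_model("surface"))`
and `boundary_z = "surface"`, after which `z_distribution()` shows the
adsorbed layer as a sharp density peak one body radius above the slab.

A YAML-driven command-line front end covering the same workflow
(`build-grids`, `simulate`, `analyze`, `fixtures`) ships in
`inst/scripts/rigidbd.R`.

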