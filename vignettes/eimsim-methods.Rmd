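---
title: "Simulating electron-ionization mass spectra by fragmentation-cascade dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating electron-ionization mass spectra by fragmentation-cascade dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eimsim)
```

## The model

In 70 eV electron-ionization mass spectrometry a molecule M is ionized to
M⁺ and left vibrationally hot; the hot radical cation decomposes on a
picosecond timescale into the fragment ions that make up its spectrum.
`eimsim` implements the stochastic simulation protocol that turns this
picture into a spectrum prediction in three stages:

1. **Conformer sampling.** The neutral molecule is equilibrated in the
   canonical ensemble (Berendsen velocity rescaling, set-point 500 K,
   12.5 ps by default) and conformers — geometry *and* nuclear
   velocities — are drawn uniformly from a subsequent 25 ps
   microcanonical trajectory (1000 snapshots by default).  Nuclei are
   propagated classically with a leap-frog integrator at a 0.5 fs step;
   we use the synchronized kick-drift-kick form, which generates the
   identical trajectory to the offset-velocity formulation while keeping
   energies well defined at integer steps.

2. **Ionization energetics.** Each production run ionizes one sampled
   conformer vertically and draws an internal excess energy (IEE)
   `E` from a unimodal Poisson-like density with mode 0.6 eV per atom,
   supported on `(0, E_impact − ε_HOMO]` with `E_impact = 70` eV.  The
   ionized orbital `j` is chosen uniformly among occupied orbitals whose
   binding offset `ε_M − ε_j` does not exceed the IEE (`M` the HOMO
   ordinal).  The ion then relaxes by internal conversion over
   `t = k_h exp(−α (ε_M − ε_j))` with `α = 0.5 eV⁻¹`, `k_h = 2` ps —
   the energy-gap law, giving the familiar 0.2–3 ps heating windows for
   valence gaps up to ~4.6 eV.  During that window the IEE is deposited
   into nuclear kinetic energy in equal per-step increments realized by
   velocity scaling, with per-atom scale factors proportional to the
   ionized orbital's Mulliken populations (set to unity at ≥ 35 atoms,
   where localized initial states are no longer a good description).

3. **Fragmentation cascades and statistical charges.**  During hot-ion
   propagation (up to 10 ps per cascade level) fragmentation is detected
   geometrically: atoms are bonded when closer than 1.2 × the sum of
   their covalent radii, and a split must persist for 3 consecutive
   checks spaced 20 steps (10 fs) apart before it counts, so transient
   stretches are ignored.  At an accepted split each fragment's vertical
   IP and internal temperature are evaluated and the unit charge is
   partitioned by the Boltzmann weight

   `C_i = exp(−IP_i / k_B T_Av) / Σ_j exp(−IP_j / k_B T_Av)`,

   where `T_Av` is the unweighted mean of the fragment internal
   temperatures at the event.  The highest-charge fragment re-enters
   propagation as a *cascade* with a fresh time budget, its weight
   multiplying all deeper weights; the others are stored.  By
   construction the stored statistical charges of one run sum to exactly
   the parent charge of 1 — the central bookkeeping theorem, tested
   against a recursive brute-force oracle on randomized cascade trees.
   Accumulating charges by fragment formula over all runs and convolving
   with natural isotope patterns on the unit-mass grid yields the final
   stick spectrum, normalized to base peak 100.

## Reconstructed functional forms

Three ingredients of the published protocol are stated only through
their constraints (the printed equation bodies are not machine-readable
in our source material), so this package adopts explicit reconstructions
and exposes them as pluggable hooks:

* **IEE density** (`sample_iee`): a gamma density anchored so its mode is
  `0.6 × n_atoms` eV and its width scales as `a·b·n_atoms`
  (`a = 0.2` eV/atom, `b = 1`), truncated at `E_impact − ε_HOMO` by
  rejection.  This honors every stated property — unimodal Poisson-type
  shape, per-atom mode, hard support bound — without claiming bit
  compatibility with any particular reference implementation; a
  `sampler` argument accepts a replacement density.
* **IC time** (`ic_time`): the single-gap exponential above.  It
  reproduces the stated zero-gap value of 2 ps exactly and the observed
  0.2–3 ps window for valence gaps, and is clamped to `[dt, 10 ps]`.
* **Charge weights** (`statistical_weights`): the softmax/Boltzmann form
  over vertical IPs at `T_Av`, computed shift-stably (minimum IP
  subtracted before exponentiation).  It is the only form consistent
  with normalization to the total molecular charge, the stated
  dependence on IPs, `T_Av` and `k_B`, and the lowest-IP-wins
  zero-temperature limit.  The `weight_fn` argument of
  `assign_and_select()` swaps it out.

Two further rules are unstated in the protocol and fixed here as design
choices: ionized-orbital selection is uniform over energetically
accessible occupied orbitals (pluggable via `weights_fn`), and heating
deposits energy uniformly in time across the conversion window.

## The provider contract and the surrogate PES

All electronic structure flows through a three-service provider
contract: `energy_gradient(mol, electronic_temperature)`,
`mo_spectrum(mol)`, and `vertical_ip(mol)`.  The electronic temperature
(300 K for ground-state stages, 5000 K during production runs) is a
contract parameter that real tight-binding or DFT backends use for
Fermi smearing of fractional occupations; it is forwarded verbatim.

The built-in surrogate is a reactive pair potential: Morse wells over a
bonded topology frozen from the reference geometry, plus a short-range
exponential repulsion (`A e^{−r/ρ}`, `A = 100` eV, `ρ = 0.08` Å)
between *non-bonded* pairs.  Restricting the repulsion to non-bonded
pairs is deliberate: the Morse inner wall already repels bonded pairs,
and keeping bonded-pair energies purely Morse makes fixture energetics
exact (a diatomic at `r_e` sits at exactly `−D_e`).  Freezing the
topology prevents distant atoms from spuriously re-bonding, which keeps
fixture fragmentation analytically predictable.  On a charged surface
every well depth is scaled by `1 − s` (`s = 0.2` by default), so
ionization weakens all bonds uniformly — the mechanism that lets a cold
neutral survive sampling yet dissociate after ionization-heating.  The
gradient is the exact analytic derivative and is verified against
central differences to 10⁻⁶ eV/Å; the surrogate is
translation/rotation invariant with forces summing to zero.

The surrogate has no electronic structure, so it accepts and ignores the
electronic temperature, and its `mo_spectrum`/`vertical_ip` services are
supplied by mock providers: a configured orbital-energy/population table
and an exact formula-keyed IP lookup with a constant fallback.  An
external engine can be attached by implementing the same three functions
(the natural transport is an XYZ file out and a keyed text file back);
nothing in the MD or bookkeeping layers changes.

## What the fixtures emulate — and what they do not

The shipped fixtures make every stage observable at desk scale:

* `make_weak_bond_dimer()` — a 6-atom CH₂–NH₂ pair joined by a 1 eV
  central bond (moiety-internal bonds 4.3–4.5 eV).  Its designed IEE of
  6 eV breaks only the central bond; the IP table (NH₂ 7 eV, CH₂ 11 eV)
  puts ≥ 95% of the charge on NH₂ at any event temperature below a few
  thousand kelvin.
* `make_cascade_chain(3)` — a C–N–O–F chain with bond strengths 0.5,
  1.35, 2.2 eV, so cleavage proceeds weakest-first; sub-chain IPs
  decrease with size, so the largest fragment keeps the charge and the
  cascade reaches depth ≥ 2 at the designed IEE of 3.5 eV.  The designed
  excitation matters: well above it, both weak bonds sever within one
  detection window and the same fragments appear in a single
  shallower event (charge conservation holds either way).

Passing these tests demonstrates that the *protocol machinery* —
integration, heating, detection, cascade bookkeeping, charge
normalization, isotope convolution, determinism — is correct.  It does
**not** demonstrate chemical accuracy for real molecules: the surrogate
PES has no barriers, rearrangements, or electronic effects, so simulated
spectra of real molecules are only meaningful through an external
quantum-chemical backend.  Reproducing published full spectra
additionally needs ~10⁸ force calls per molecule, far beyond desk scale.

## Numerical choices and degenerate inputs

* Units: Å, fs, eV, amu; `1 amu Å² fs⁻² = 103.6427 eV` and
  `k_B = 8.6173×10⁻⁵ eV/K` are centralized in `eims_constants`.
* Heating solves a quadratic for the velocity-scaling amplitude each
  step so the kinetic-energy gain is exact; a completely frozen molecule
  receives a deterministic alternating-axis kick pattern with zero net
  momentum, rescaled to the exact increment.  Momentum is conserved by
  the integrator but not by population-weighted heating (a localized
  kick that carries momentum is exactly the intended physics).
  If fragmentation is accepted mid-window, the remaining increments are
  dropped — the cascade fragment re-enters propagation unheated.
* Fragment internal temperature removes center-of-mass translation
  always and rigid rotation for N ≥ 3 (via the inertia-tensor
  pseudo-inverse, so linear geometries are safe); degrees of freedom are
  3N−6 (nonlinear), 3N−5 (linear), 1 for diatomics — whose full
  relative motion is counted against one vibration — and single atoms
  report 0 K.  The 3N−6 choice (vs 3N) raises event temperatures
  slightly and thereby softens charge partitions; it is the
  thermodynamically standard count for internal energy.
* Charge-weight ties break to the lowest fragment index; `which.max`
  makes this deterministic under fixed seeds.
* Zero-temperature or negative `T_Av` falls back to the lowest-IP-wins
  limit with a warning; empty IP lists are an error.
* Isotope convolution uses integer mass numbers (unit-mass
  aggregation), iterative convolution with binary exponentiation per
  element, and optional relative-abundance pruning; with pruning off it
  conserves total abundance to 10⁻⁹ and matches exhaustive isotopologue
  enumeration for small formulas.  Heavy elements whose most abundant
  isotope does not dominate (Sn, Te, and similar) have nominal-mass
  labels that disagree with common average-mass-rounded spectrum labels;
  `nominal_mz` always uses the most-abundant-isotope convention.
* Per-run seeds derive from the master seed by 31-bit Lehmer-style
  mixing, so any worker count and scheduling order give bitwise
  identical spectra; the reduction is an order-independent sum of exact
  per-run charge maps.

## Problem sizes used in the shipped tests

The test suite exercises the full protocol on the 4–7-atom fixtures with
shortened stage durations (hundreds of fs of equilibration and sampling,
production capped at 1–1.5 ps, 4–24 runs), 10⁴-step conservation runs
for the integrator, and 2×10⁵–10⁶-draw samples for the IEE density.
These sizes were chosen so the entire suite completes in about a minute
while every quantitative claim above is still measured, not assumed; all
stage durations scale to the full defaults through the configuration
alone.

## Known limitations

* Only singly charged cations; no adducts, no high-resolution masses.
* No non-adiabatic charge hopping: the charge partition is purely
  statistical in the vertical IPs, so effects where the charge does not
  follow the lowest-IP fragment are absent by construction.
* The Berendsen thermostat does not sample the canonical ensemble
  exactly; for conformer generation at this scale the bias is
  irrelevant, and the thermostat choice is configurable at the code
  level.
* The IEE/IC reconstructions above are protocol-compatible, not
  bit-compatible, with any specific published implementation.
* `T_Av` is evaluated at the fragmentation event, before any further
  relaxation of the daughter ion.
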