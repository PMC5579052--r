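---
title: "Cluster-equilibrium thermodynamics of water and its ionic product"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-equilibrium thermodynamics of water and its ionic product}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcewater)
```

## The model

Quantum Cluster Equilibrium (QCE) theory describes a one-component fluid as a
chemical equilibrium among molecular clusters. Each cluster $i$ — defined by
its composition ($n_i$ monomer units, here water molecules, optionally with
one hydronium/hydroxide ion pair), its adiabatic interaction energy
$\Delta E_i$ relative to separated monomers, its harmonic frequencies,
rotational constants, symmetry number and volume $v_i$ — contributes a full
partition function

$$q_i = q^{\mathrm{trans}}_i\, q^{\mathrm{rot}}_i\, q^{\mathrm{vib}}_i\,
        q^{\mathrm{elec}}_i$$

in the rigid-rotor/harmonic-oscillator/electronic factorization. Two
empirical van der Waals corrections couple the clusters to their
surroundings:

* `a_mf` (J L mol⁻²) lowers each cluster's electronic energy by
  $a_\mathrm{mf} n_i / V_m$ — a mean-field attraction per monomer that grows
  with density;
* `b_xv` (dimensionless) scales the summed occupied cluster volume into an
  exclusion volume $V_\mathrm{ex} = b_{xv} \sum_i N_i v_i$ that is removed
  from the translational free volume.

At fixed $(T, p)$ and one mole of monomer, the simultaneous equilibria
$n\,\mathrm{H_2O} \rightleftharpoons (\mathrm{H_2O})_n$ give the mass-action
conditions $\ln N_i = \ln q_i + n_i(\ln N_1 - \ln q_1)$ under the constraint
$\sum_i n_i N_i = 1$; differentiating the Helmholtz energy with respect to
volume yields the vdW-type isotherm

$$p = \frac{RT \sum_i N_i}{V - V_\mathrm{ex}}
      - \frac{a_\mathrm{mf} \sum_i n_i N_i}{V^2},$$

whose admissible cubic roots are the candidate phase volumes. `qce()`
iterates populations and volume to a joint fixed point from two initial
branches — a gas-like start at $V = RT/p$ and a liquid-like start near the
packed cluster volume — and selects the converged branch of minimal Gibbs
energy $G = A + pV$, with $A$ evaluated by Stirling's approximation over
particle counts. The boiling point is the temperature at which the two
branch Gibbs energies cross; `transition_temperature()` detects it from the
jump in $V(T)$ and refines it by bisection on the crossing.

Autoionization enters through net-neutral ion-pair (IP) clusters carrying
one hydronium and one hydroxide each. Because these lie tens of kJ/mol above
their neutral isomers, their equilibrium populations are Boltzmann-tiny, and
the ionic product follows directly from the converged populations:

$$K_W = \frac{\sum_i n_i(\mathrm{H_3O^+})\, n_i(\mathrm{OH^-})\, N_i^2}{V^2},
\qquad pK_W = -\lg K_W ,$$

with $N_i$ in moles of cluster per mole of monomer and $V$ in litres per
mole of monomer, so $K_W$ is in mol² L⁻². This diagonal ionic-cluster sum is
the default; `ion_product(state, mode = "product")` provides the
conventional product of total ion concentrations
$[\mathrm{H_3O^+}][\mathrm{OH^-}]$ instead. The two coincide whenever one IP
cluster dominates; with several comparably populated IP clusters they
differ, and we default to the diagonal form because it is the form the QCE
populations directly define (each IP cluster carries its own anion–cation
pair; cross terms would count ion pairs that never coexist in one cluster).

## Numerical choices

**Log-space arithmetic everywhere.** Cluster partition functions span
hundreds of orders of magnitude (a gas-phase ionization constant is of order
$10^{-285}$), so populations, $q$ values and $K_W$ are carried as
logarithms; `solve_populations()` brackets and then Newton-iterates on
$\ln N_1$ (the mass constraint is strictly increasing in $N_1$, so the root
is unique), and `equilibrium_constant()` computes $pK$ before ever
exponentiating.

**Fixed-point iteration.** Volume updates are damped by a factor 0.5;
convergence requires relative changes in both $V$ and $\ln N_1$ below
10⁻¹⁰, with a 500-iteration cap. Non-convergence is a warning carrying the
final residuals; a temperature at which neither branch converges is an
error. When both branches land on the same fixed point (their volumes agree
within 1 %), the state is treated as single-phase and no Gibbs crossing is
reported there. At a genuine tie in $G$ (within the solver's resolution,
10⁻⁹ relative) the denser liquid-like branch is preferred.

**Conventions.** Interaction energies are taken as pure electronic
(ZPE-exclusive), so the vibrational partition function includes the
zero-point factor by default; `include_zpe = FALSE` flips the convention for
data sets whose energies already contain ZPE. No frequency scaling is
applied by default (`scale` exposes a uniform factor). Low-frequency
intermolecular modes are kept harmonic — no free-rotor interpolation — which
overestimates their entropy somewhat at high temperature; this is a known
limitation shared by the plain RRHO treatment. Symmetry numbers default
to 1 when a data set does not state them. All species are treated as
nonlinear tops; atomic or linear records are rejected. Physical constants
are pinned to CODATA 2018 in one table (`qce_constants()`).

**Cluster volumes.** `cluster_volume()` integrates the union of Bondi
spheres on a regular grid (default spacing 0.05 Å, error below 0.5 % for
single spheres) rather than reconstructing a solvent-excluded surface: the
QCE exclusion volume only needs mutually consistent relative volumes, and
any uniform scale error is absorbed into `b_xv`. The "inflated" mode adds a
probe radius (default 1.4 Å) to every sphere for users who want a
solvent-accessible envelope.

## Calibration

The two empirical parameters are determined from two standard-state
references — the liquid density at a reference temperature and the boiling
temperature at the working pressure. `fit_qce()` minimizes

$$w_\rho \left(\frac{\rho(T_\mathrm{ref}) - \rho_\mathrm{ref}}
{\rho_\mathrm{ref}}\right)^2 +
w_T \left(\frac{T_b - T_{b,\mathrm{ref}}}{T_{b,\mathrm{ref}}}\right)^2$$

by a 20×20 grid search over the parameter box followed by Nelder–Mead
refinement from the best cell; a missing boiling transition or solver
failure contributes a penalty of 10⁶, and a zero weight drops that
reference. Inside the objective the boiling point is located by bisection on
the gas/liquid Gibbs crossing (coarse 10 K scan, then bisection to 0.01 K)
rather than by sweeping a full 1 K isobar — the same definition the isobar
refinement uses, at roughly a tenth of the cost.

The default search box is `a_mf` ∈ [0, 800] J L mol⁻², `b_xv` ∈ [0.5, 2].
The attraction scale follows from water itself: the literature vdW constant
of water is about 0.55 J m³ mol⁻² = 550 J L mol⁻², and we find empirically
that below a few tens of J L mol⁻² no liquid branch can be sustained at all
for water-like cluster sets. The lower `b_xv` bound stays away from the
regime in which the equation of state loses its repulsive wall and the
liquid root collapses to unphysical densities above 4 g/cm³.

## The synthetic fixture

`synthetic_cluster_set()` generates a seeded, fully deterministic
water-like cluster set: neutral clusters of 1..N monomers (a
hydrogen-bonded chain for the dimer, rings with $n$ hydrogen bonds for
$n \ge 3$) at about −25 kJ/mol per hydrogen bond — the electronic
interaction scale of DFT water rings — with 9n − 6 harmonic modes (6(n−1)
low intermolecular ones plus bend/stretch groups with H-bond red shifts),
rotational constants falling as $n^{-5/3}$, and volumes of about
20 Å³ per monomer. For every size from the pentamer up, one ion-pair isomer
is added whose interaction energy is *exactly* the neutral isomer's plus
`ip_destabilization` (default 80 kJ/mol, which puts the fixture's ambient
$pK_W$ in the mid-20s — deliberately on the destabilized side of real
water); the largest sizes (8 and 10 in the packaged 18-cluster set,
`synthetic_water_set()`) carry a second IP isomer, mirroring the coexisting
ion-pair motifs of real cluster sets.

At the documented operating point `synthetic_reference_parameters()`
(a_mf = 500 J L mol⁻², b_xv = 1.43, chosen once from a coarse water-likeness
scan), the seed-1 fixture gives a liquid of 0.997 g/cm³ at 298.15 K and
boils at 383 K at 1 atm; across seeds the boiling point moves over roughly
380–440 K because the per-cluster energy jitter of ±1 kJ/mol per hydrogen
bond acts on all ten bonds of the decamer at once.

What the fixture does *not* emulate: cooperative (non-pairwise) hydrogen-
bond strengthening with cluster size, three-dimensional polycyclic motifs
(all neutral clusters are rings), anharmonicity, and any quantitative
correspondence with a particular electronic-structure method. Passing
property tests on this fixture therefore demonstrates the correctness of
the solver, the thermodynamics and the calibration machinery — not the
predictive accuracy of any specific quantum-chemical cluster data set, which
must be supplied by the user through `load_cluster_set()`.

## Problem sizes used in the checks

The packaged checks run a 127-point isobar (274–400 K, 1 K) for mass
conservation and ionic-product monotonicity, a 99-point sweep (274–470 K,
2 K) for the boiling point, the 20×20 calibration grid with Nelder–Mead
refinement for parameter recovery, twelve randomized 2–3-cluster systems
against a dense brute-force population scan, and single-sphere volume grids
at 0.05 Å spacing. On one CPU the whole set completes in roughly ten
minutes, dominated by the calibration grid.

## Known limitations

* Single-component sets only; no binary mixtures, no temperature-dependent
  `a_mf`/`b_xv`.
* RRHO partition functions without anharmonic, hindered-rotor or
  excited-electronic-state corrections.
* The Gibbs comparison sees only the two fixed points actually reached;
  metastable branches beyond gas/liquid initialization are not enumerated.
* No activity-coefficient or ionic-strength corrections in $K_W$.
* Electronic-structure input (energies, frequencies, geometries) is taken
  as given; the package neither reads quantum-chemistry program output
  directly nor judges its quality.
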