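# qcewater

Quantum Cluster Equilibrium (QCE) thermodynamics for water, extended with
net-neutral ion-pair clusters so that the temperature-dependent ionic
product K_W — and hence pK_W = −lg K_W, the quantity behind "pH = 7" — can
be predicted from cluster-level quantum-chemistry data.

QCE describes a liquid as a chemical equilibrium among clusters
(n H₂O ⇌ (H₂O)ₙ, plus ionized isomers
n H₂O ⇌ [H₃O⁺](H₂O)ₙ₋₂[OH⁻]). Each cluster carries a full
rigid-rotor/harmonic-oscillator/electronic partition function built from
its interaction energy ΔEᵢ, harmonic frequencies, rotational constants and
volume; two empirical van der Waals corrections — a mean-field attraction
`a_mf` and an exclusion-volume scale `b_xv` — couple the clusters to their
surroundings. At fixed (T, p) the package solves the simultaneous
mass-action equations together with the vdW-type equation of state

    p = RT ΣᵢNᵢ / (V − V_ex) − a_mf ΣᵢnᵢNᵢ / V²,   V_ex = b_xv ΣᵢNᵢvᵢ

to a self-consistent fixed point on both a gas-like and a liquid-like
branch, selects the phase of minimal Gibbs energy, and evaluates the ionic
product from the converged ion-pair populations:

    K_W = Σᵢ nᵢ(H₃O⁺) nᵢ(OH⁻) Nᵢ² / V²      [mol² L⁻²]

The two vdW parameters are calibrated against exactly two experimental
numbers — the liquid density at 298.15 K and the boiling point — and
everything else follows from the cluster data. All population algebra runs
in log space: the relevant equilibrium constants span ~300 orders of
magnitude (the gas-phase ionization of a free water molecule has
K ≈ 10⁻²⁸⁵; the liquid enhances this by ~10²⁷¹).

Intended users: physical/theoretical chemists with per-cluster data from an
electronic-structure code (transcribed into the package's plain-text
cluster-set format) who want liquid-phase thermodynamics and ion
concentrations out of it, and method developers who need a transparent,
fully testable reference implementation of ion-pair-extended QCE.

## Worked example

The packaged synthetic 18-cluster fixture (neutral clusters of 1–10 waters
plus ion-pair isomers from the pentamer up) stands in for a real
quantum-chemistry cluster set:

```r
library(qcewater)
cs  <- synthetic_water_set(seed = 1)          # 18 clusters, deterministic
iso <- qce(cs, synthetic_reference_parameters(),
           T = seq(274, 400, by = 2))         # 1 atm isobar, both branches
summary(iso)
#> QCE isobar summary ('synthetic_water_seed1', p = 1.013e+05 Pa)
#>   a_mf = 500 J L/mol^2, b_xv = 1.43
#>   64 grid points in [274.00, 400.00] K; 55 liquid-like
#>   boiling transition at 382.98 K
#>   nearest 298.15 K (T = 298.00): density 0.9975 g/cm^3, phase liquid-like, pKw 24.99
#>   pKw range on grid: 19.60 .. 59.85
```

The model liquid has water's ambient density, boils ten degrees high, and
its ionic-product curve falls with temperature like the real one (the
absolute pK_W ≈ 25 instead of 14 reflects the fixture's deliberately strong
80 kJ/mol ion-pair destabilization):

```r
kw <- kw_curve(iso)
kw[kw$T %in% c(274, 298, 350), ]
#>      T           Kw      pKw
#> 1  274 3.423390e-28 27.46554
#> 13 298 1.024616e-25 24.98944
#> 39 350 8.139078e-22 21.08942
```

Calibrating `(a_mf, b_xv)` against a density and a boiling point, and the
kinetics of the rate-limiting ionization step of the cyclic water pentamer
(from the packaged stationary-point table), round out the workflow:

```r
fit <- fit_qce(cs, fit_spec(reference_density = 0.9970,
                            reference_boiling_T = 373.15))  # ~8 min
reaction_barriers(read_reaction_profile())
#>   from  to  dE_kcal  dG0_kcal is_barrier
#> 1  W5c W5p  3.49962  4.887044      FALSE
#> 2  W5p W5x 18.25488 19.109546       TRUE
equilibrium_constant(389, 298.15)$pK      # gas-phase water splitting
#> [1] 285.139
```

The ~19 kcal/mol double-proton-transfer barrier converts to a room-
temperature Eyring rate via `eyring_rate(19.11, 298.15)`; real cluster sets
load from a YAML manifest directory via `load_cluster_set()`, and
`cluster_volume()` supplies Bondi-sphere volumes from XYZ geometries. A
command-line front end (`inst/cli/qce.R`) exposes `fit`, `isobar`, `kw`,
`kinetics` and `volume` subcommands over YAML run configs.

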