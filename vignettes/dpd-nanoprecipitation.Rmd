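---
title: "Mesoscale DPD of PLA nanoparticle formation and drug loading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesoscale DPD of PLA nanoparticle formation and drug loading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`dpdnano` simulates the self-assembly of poly(lactic acid) (PLA)
nanoparticles and their loading with amphiphilic lipopeptides (Pam1CSK4,
Pam3CSK4) or a hydrophobic small molecule (vitamin E) with dissipative
particle dynamics (DPD).  DPD evolves soft beads — each representing a group
of atoms — under three pairwise forces inside a cutoff $r_c$:

* a conservative linear repulsion $F^C_{ij} = a_{ij}(1 - r_{ij}/r_c)\,\hat e_{ij}$,
* a dissipative drag $F^D_{ij} = -\gamma (1 - r_{ij}/r_c)^2 (\hat e_{ij}\cdot v_{ij})\,\hat e_{ij}$,
* a random kick $F^R_{ij} = \sigma (1 - r_{ij}/r_c)\,\theta_{ij}\,\Delta t^{-1/2}\,\hat e_{ij}$,

with $\sigma^2 = 2\gamma k_BT$ (fluctuation–dissipation) so that the last two
act as a momentum-conserving thermostat.  Chain molecules add harmonic bonds
$F^B = -k_b (r - r_0)\hat e$.  All forces are pairwise antisymmetric, so
total momentum is conserved exactly and hydrodynamics is preserved — the
property that lets DPD reach the microsecond-scale collective dynamics of
nanoprecipitation that atomistic MD cannot.

### Bead scheme and parameters

One water bead (W) represents three water molecules (54 Da, 3.23 Å radius);
PLA is a linear chain of 70 lactic acid beads (LA); the lipopeptides are
built from lysine (K), serine (S), modified cysteine (C), modified glycerol
(G) and 5-bead palmitoyl tails (F); vitamin E is one chromanol bead (CHR)
plus three 5-carbon tail beads (C5).  Repulsion parameters come from
Hildebrand solubility parameters via the Flory–Huggins route
$\chi_{ij} = (v/RT)(\delta_i - \delta_j)^2$ and $a_{ij} = 25 + 3.5\,\chi_{ij}$;
the two parameter tables shipped with the package
(`default_interaction_matrix("pam")`, `"vitE"`) are used verbatim for all
simulations.  Their like-pair value is 78, not the 25 that $\chi_{ii}=0$
would give: the tables follow the stiffer like-pair repulsion appropriate
for a three-water bead, and `build_matrix_from_solubilities()` therefore
applies the $25 + 3.5\chi$ rule to off-diagonals only, with a configurable
diagonal convention (default 78).

Key orderings in the table drive all the physics reported here:
water–lysine (26.7) is far below water–water (78), so K coronas are
strongly hydrated; water–tail (91.3) and water–PLA (91.3) are above it, so
tails and PLA demix from water; tail–PLA (25.1) is strongly compatible, so
lipopeptides anchor to PLA through their tails.

### Units

Reduced units: $r_c = 6.46$ Å (one W-bead diameter), $k_BT = 1$, the W mass
as mass unit.  Water at 1 g/cm³ then gives the canonical DPD liquid density
$\rho = 3$ beads/$r_c^3$, which every builder uses to fill space.  Elapsed
time is reported through the study's convention of 3 ps represented per DPD
step, so 10 ns ≙ 3334 steps; this mapping is bookkeeping only and does not
enter the dynamics.

### Integration

A modified velocity–Verlet scheme with velocity predictor $\lambda$
advances the system; a linked-cell grid (cell edge ≥ $r_c$, all-pairs
fallback for boxes under 3 cells) makes each step $O(N)$.  Defaults:
$\gamma = 4.5$, $\sigma = 3$, $\Delta t = 0.04$, $k_b = 4$, $r_0 = 0$.  We
use $\lambda = 0.65$, the value recommended for $\gamma = 4.5$: with the
stiff $a_{ii} = 78$ fluid, $\lambda = 0.5$ at this time step runs about 4%
hot, while $\lambda = 0.65$ keeps the kinetic temperature within ~2% of the
target (the package's thermostat-fidelity test asserts 3%).  All constants
are exposed through `dpd_params()`.  Pairwise random numbers are drawn from
a uniform unit-variance distribution in a deterministic pair order, so a
seed reproduces a trajectory bit-exactly on one platform and momentum is
conserved to accumulator precision (asserted at $10^{-6} N$ over $10^4$
steps).

## The three experiment geometries

`random_mixed_box()` (concentrated solutions), `droplet_setup()`
(nanoprecipitation: a 130 Å droplet of water + PLA + cargo centred in a
280 Å water box, compositions 201:67:1 water:PLA:Pam and 750:125:117
water:PLA:vitamin E, the latter an 8% w/w vitamin E/PLA loading) and
`slab_setup()` (saturation: a 100 Å PLA layer at one end of a
500×100×100 Å water box with dispersed lipopeptide).  Chains are grown as
random walks with bond length $r_c/2$; soft cores tolerate the initial
overlaps, which a 100-step warm-up at $\Delta t/10$ (`dpd_warmup()`)
relaxes before production.  Velocities are drawn at $k_BT = 1$ with the net
momentum removed exactly.

### The concentration convention

The concentrated-solution studies state "3%, 10% and 30% (number of
molecules vs water molecules)".  Read literally as a molecule-count ratio,
30% of a 12-bead amphiphile yields a box whose beads are 78% amphiphile —
a solvent-free melt.  That composition cannot produce the reported
morphology (discrete micelles and wormlike micelles dispersed in water),
which matches cryo-TEM of aqueous solutions.  Read as the solute *bead*
(volume) fraction — the convention of mesostructure builders — 30% solute
leaves 70% water and reproduces the reported structures.
`random_mixed_box()` implements both: `basis = "molecule"` is the literal
contract and the default; the shipped concentrated-solution scenarios use
`basis = "bead"`.  The slab-saturation scenarios keep the molecule basis:
their 1–10% ratios stay water-dominated either way and the saturation
fractions are defined per molecule.

## Observables

All estimators operate on configurations under periodic boundaries; centres
of mass use the circular (angle-average) method, so every metric is
invariant under periodic-image shifts.

* **Clusters** (`find_clusters`): molecules are connected when filtered
  beads (default: the hydrophobic species F/LA/CHR/C5) lie within a cutoff
  (default $1\,r_c$); clusters are connected components.  In crowded boxes
  this single-linkage rule chains visually distinct micelles through
  grazing single-bead contacts — we observed spanning components whose
  bounding volume still holds bulk-density water.  `min_contacts` requires
  a number of shared bead-pair contacts for co-membership;
  `micelle_census()` defaults it to one 5-bead tail segment, the structural
  unit whose burial defines membership of a micelle core.  The default
  `min_contacts = 1` preserves the plain contact-graph contract.
* **Micelle diameter** (`cluster_diameter`): mass-weighted radius of
  gyration mapped to the uniform-sphere equivalent $D = 2\sqrt{5/3}\,R_g$
  (a uniform ball of radius $R$ has $R_g^2 = \tfrac{3}{5}R^2$).
* **Morphology** (`shape_class`): gyration-tensor eigenvalues
  $\lambda_1 \ge \lambda_2 \ge \lambda_3$; wormlike when
  $\sqrt{\lambda_1/\lambda_3} > 3$ (tunable).
* **Bilayer thickness** (`bilayer_thickness`): $2\sqrt{3\lambda_3}$, the
  full width of the uniform slab with the same smallest-axis second moment
  (a slab of half-thickness $t$ has $\lambda_3 = t^2/3$); validated against
  that closed form in the tests.
* **Particle diameter** (`particle_diameter`): twice the radius where the
  radial LA density falls to half its core plateau; degenerate clusters
  (< 100 beads) fall back to the gyration diameter with a flag.
* **Radial ordering** (`radial_ordering`): per-species mean distance from
  the particle centre; assembled lipopeptide particles satisfy
  $\langle r(K)\rangle > \langle r(F)\rangle$ (heads out, tails buried).
* **Encapsulated fraction** (`encapsulated_fraction`): a solute molecule is
  *inside* when any bead lies within the cutoff of a host LA bead,
  *micelle* when it instead belongs to a solute-only cluster of ≥ 3
  molecules, else *free*.
* **Water exclusion** (`water_exclusion`): W density inside half the
  particle radius over the box-average W density.

Headline numbers are means over the final 20% of snapshots
(`tail_snapshots`) where a trace is available; single-snapshot values are
reported for end states.

## What the generator emulates — and what it does not

The builders reproduce the study's compositions, densities and length
scales, and the engine the collective demixing dynamics.  They do not
emulate: electrostatics (lysine charge enters only through the repulsion
table), the acetone/ethanol co-solvents of the laboratory protocol (the
mesoscale model is aqueous), polymer polydispersity, or release kinetics
(hours-scale processes outside DPD's reach).  Desk-scale runs in the tests
use reduced boxes (13–20 $r_c$) and 10–18 ns; at these sizes aggregate
numbers and encapsulated fractions carry finite-size noise, which is why
the quantitative checks use the tolerance bands stated with each test
rather than exact values.  Passing them shows the pipeline reproduces the
reference morphologies and trends at the stated scales — not that the model
is predictive for chemistry outside the shipped parameter tables.

## Numerical choices

* Thermostat constants, $\lambda$, bond constants: above; all in
  `dpd_params()`.
* Cluster cutoff $1\,r_c$, micelle minimum 3 molecules, aspect threshold 3,
  half-max radial criterion: explicit, tunable operationalizations of
  observables the study measured visually.
* Coincident soft cores (r = 0): the conservative direction is undefined;
  the pair contributes energy but no force for that instant.
* Degenerate (collinear/planar) clusters classify as wormlike
  ($\lambda_3 \to 0$).
* Cell lists rebuild every step; boxes smaller than 3 cells per dimension
  fall back to exact all-pairs summation (the two paths agree to
  $10^{-12}$, asserted).
* Droplet scenarios do not fill the droplet interior to $\rho = 3$: the
  reported contractions (260 → 150 Å with lipopeptide cargo, 260 → 140 Å
  with vitamin E) are mass-consistent only if the droplet starts as loose
  polymer coils near $0.6\rho$ that collapse into a compact particle, which
  fixes the shipped composition scales (4 and 2).
* Problem sizes in the tests: thermostat and momentum checks use 5–6 $r_c$
  water boxes; the quantitative morphology runs use 20 $r_c$ boxes for
  3334 steps and the dilute (3%) checks 17 $r_c$ boxes; droplet checks use
  a 12.5 $r_c$ droplet in a 26 $r_c$ box (2000 steps) and the saturation
  surrogate a 16 × 8 × 8 $r_c$ box with a 4 $r_c$ layer (10000 steps) —
  sizes at which the qualitative contracts are stable across seeds.

## Known limitations

* The simulated Pam3CSK4 bilayer is thinner than the experimental SAXS
  value (5.3 nm): every convention we measured — slab-equivalent
  $2\sqrt{3\lambda_3}$ on isolated clusters, local FWHM, head-group
  shell-to-shell distance — gives 2.5–3.6 nm, insensitive to the bond rest
  length between 0 and 1 $r_c$.  Soft cores let the two leaflets
  interdigitate, which halves the core width; the morphology itself
  (wormlike bilayer network, dry core, lysine corona) is reproduced.
* The morphology of the 30% Pam3CSK4 system is kinetically slow: from a
  random start the wormlike aggregates fuse into one spanning network
  within a 20 $r_c$ box, so thickness must be measured locally
  (`local_bilayer_thickness`) rather than per isolated cluster.
* Aggregation numbers at desk scale are bounded by the box; diameters of
  the largest aggregates saturate near the box size.
* The saturation fractions at full scale (300 ns, 500 Å box) are outside
  the test budget.  The suite asserts the monotone non-increase on a
  reduced slab, where the layer stays below its capacity and all three
  fractions sit at 1.0 — the trend holds degenerately; the strict
  100/75/60% split is a full-scale, long-run observable.  Longer desk
  columns produce kinetics-dominated (non-monotone) fractions instead.

## A worked session

```{r example}
library(dpdnano)

mat <- default_interaction_matrix("pam")
cfg <- random_mixed_box(c(130, 130, 130), build_template("Pam1CSK4"),
                        solute_pct = 30, seed = 1, basis = "bead")
cfg <- dpd_warmup(cfg, mat, dpd_params(seed = 2))
tr  <- dpd_run(cfg, mat, dpd_params(seed = 2), ns_to_steps(10), stride = 1667)

fin <- final_snapshot(tr)
micelle_census(fin, "Pam1CSK4")
```
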