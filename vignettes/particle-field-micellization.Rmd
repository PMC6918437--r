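---
title: "Hybrid particle-field MD for copolymer micellization: model and methods"
author: "hpfmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid particle-field MD for copolymer micellization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpfmd)
```

## The model

`hpfmd` simulates coarse-grained amphiphilic block copolymers in mixed
solvents with *hybrid particle-field molecular dynamics* (MD-SCF). Bonded
interactions are ordinary particle-particle forces, but all non-bonded
interactions are replaced by a mean field: each bead of species $K$ feels an
external potential that is a functional of the smoothed per-species number
densities $\phi_K(\mathbf r)$ on a periodic mesh,

$$W[\{\phi_K\}] = \int d\mathbf r\,\Big(\tfrac12\sum_{KK'} \chi_{KK'}RT\,
\frac{\phi_K\phi_{K'}}{\phi_0} + \frac{1}{2\kappa}\,
\frac{(\sum_K\phi_K-\phi_0)^2}{\phi_0}\Big), \qquad
V_K = \frac{\delta W}{\delta \phi_K},$$

so that

$$V_K(\mathbf r) = \sum_{K'} \chi_{KK'}RT\,\frac{\phi_{K'}(\mathbf r)}{\phi_0}
 + \frac{1}{\kappa}\,\frac{\sum_K \phi_K(\mathbf r) - \phi_0}{\phi_0}.$$

$\chi_{KK'}$ are Flory-Huggins parameters, $\phi_0$ is the reference total
bead density, and $1/\kappa$ penalizes total-density fluctuations
(relaxed incompressibility). Two conventions in the field literature differ
on whether the incompressibility term enters the Hamiltonian linearly or
quadratically; only the quadratic form is dimensionally consistent with the
potential above, so the quadratic energy is implemented — its functional
derivative is exactly the potential the forces use, which the test suite
verifies numerically.

Because the potential is *local* in the densities, the force on a bead is
the negative interpolated mesh gradient of its species' potential. Density
fields are expensive relative to the cheap bonded forces, so they are
refreshed only every `updateInterval` steps (default 300) and *frozen* in
between ("stale-field" dynamics); between refreshes, forces are interpolated
from the frozen mesh at the current bead positions.

### The coarse-grained chemistry

The bundled model maps a Pluronic P123 chain (EO$_{20}$PO$_{70}$EO$_{20}$)
onto 18 beads, EO$_2$PO$_{14}$EO$_2$, with 9 ethylene-oxide or 5
propylene-oxide monomers per bead; one water bead lumps 20 molecules, one
ethanol bead 6, one turpentine-oil bead 2. All beads share a 600 A^3 volume,
which is what lets a single total-density field express incompressibility.
Consecutive beads interact through harmonic bonds
$V(R)=\tfrac12 K_b (R-R_0)^2$ with $R_0 = 1.12$ nm and
$K_b = 10{,}000$ kJ/mol/nm$^2$; there are no angular terms.

### Parameterization

Where Hildebrand solubility parameters $\delta$ are available, chi comes
from regular-solution theory,
$\chi_{12} = V_{\rm bead}(\delta_1-\delta_2)^2 / (k_B T)$
(`chiFromSolubility()`); literature chi values quoted at a smaller bead
volume rescale linearly in volume (`rescaleChi()`); the engine consumes
$\chi RT$ in kJ/mol (`chiToEnergy()`). `referenceChiMatrix()` assembles the
full 5x5 matrix of the bundled model.

Three numerical decisions deserve a note:

* **Two temperatures.** The solubility-parameter evaluations use 298 K
  (the convention under which the literature values 14.3 (oil-ethanol) and
  6.4 (PEO-ethanol) reproduce to two significant figures), while the
  $\chi \to \chi RT$ conversion uses the simulation temperature 303 K (the
  convention under which the bundled energy table reproduces). Both are
  explicit arguments, never hard-coded.
* **Literature constants.** Three pairs are stored as the literature values
  the parameterization actually used rather than derived: PPO-ethanol
  ($\chi = 10.0$; the solubility route gives 9.33 and no published
  derivation closes that gap), PEO-oil (21.0 kJ/mol) and water-ethanol
  (0.76 kJ/mol, equal to PEO-water). `chiFromSolubility()` still exposes
  the 9.33 so the discrepancy is visible rather than silently patched.
* **Normalization.** Densities enter the potential divided by $\phi_0$, so
  $\chi RT$ carries the energy units and the potential is in kJ/mol
  directly. Whether the mean-field convention normalizes densities is a
  genuine ambiguity of the formulation; this choice makes the uniform melt
  at $\phi_0$ an exact zero of both potential and energy.

## Discretization choices

* **Mesh.** Cell counts are the nearest integer to box/2.1 nm per axis and
  the actual cell size is recomputed from the box. 2.1 nm resolves the
  micelle core-shell structure while keeping the density per cell well
  sampled at $\phi_0 = 0.725$ beads/nm$^3$ (about 6.7 beads per cell).
* **Deposition and interpolation.** Cloud-in-cell (trilinear) in both
  directions, with mesh gradients by central finite differences. Using the
  *same* kernel for deposition and force interpolation makes the total
  field force vanish identically (discrete translation symmetry), so
  momentum is conserved exactly whenever the field is current. With stale
  fields the total force is only zero at refresh steps — an inherent,
  deliberate approximation of the method. The energy-consistency of the
  force (force = $-\partial W/\partial \mathbf r_i$) holds to $O(h^2)$ on
  mesh-resolved fields and is verified at $10^{-4}$ on a fine quasi-1-D
  mesh in the tests.
* **Incompressibility strength.** $1/\kappa$ defaults to 10 kJ/mol — the
  order of the chi table's entries, i.e. "small enough" compressibility to
  relax density fluctuations without stiffening the equations of motion.
* **Integration.** Velocity Verlet at dt = 0.03 ps, NVT at 303 K by
  Andersen collisions at $\nu = 20$/ps. The per-step collision probability
  is the exact $1-e^{-\nu\,dt}$ rather than $\nu\,dt$. The printed collision
  frequency is aggressive — dynamics are strongly overdamped — but it is
  the protocol's value and is configurable. A step that moves any bead
  farther than one mesh cell aborts the run with a blow-up error.
* **Bead masses.** The mapping does not define masses; all species default
  to the water-bead mass (20 x 18.015 u ~ 360 u), configurable per species.
  At this level dynamics are fictitious anyway (mean-field kinetics are
  roughly a thousand-fold faster than atomistic), so equal masses are the
  neutral choice.
* **Randomness.** The MD loop uses its own xoshiro256++ stream seeded from
  the state's integer seed, so trajectories are bit-reproducible and
  independent of R's RNG state; builders use R's RNG under `set.seed`.

## Analysis definitions

* **Aggregates** are connected components of the chain contact graph:
  two chains join when any pair of their *core-species* (PPO) beads lies
  within the cutoff under minimum image. The criterion is single linkage
  because hydrophobic cores define micelles; the default cutoff 1.36 nm is
  1.3 bead diameters and results should always be reported with the cutoff
  used. Unimers count in $\langle P\rangle_n = \sum_i P_i n_i$ by default;
  `minSize` supports bookkeeping that treats free chains separately.
* **Shape.** The gyration tensor is accumulated after minimum-image
  unwrapping (chains unwrapped bead-by-bead along the backbone, then whole
  chains shifted by lattice vectors toward the running aggregate center;
  valid for aggregates smaller than half the box). Eigenvalues
  $\lambda_1\le\lambda_2\le\lambda_3$ give
  $R_g^2 = \lambda_1+\lambda_2+\lambda_3$ and the asphericity
  $Q = [(\lambda_2-\lambda_1)^2 + (\lambda_3-\lambda_1)^2 +
  (\lambda_3-\lambda_2)^2]/[2(\lambda_1+\lambda_2+\lambda_3)^2]$,
  0 for a sphere and 1 for a rod; a single bead is assigned $Q = 0$.
* **Radial profiles** follow the four-step shell procedure: micelle COM,
  minimum-image distances, per-species counts divided by shell volume
  $\tfrac{4\pi}{3}(r_{\rm out}^3 - r_{\rm in}^3)$ (0.5 nm bins by default),
  averaged over micelles with equal weight.
* **Diffusion** comes from time-origin-averaged MSD of unwrapped
  coordinates, $D = $ slope/6 over a configurable window.

## What the synthetic systems do and do not show

All test inputs are generated: random-walk chains in a solvent bath
(`randomConfiguration()`) and geometric core-shell fixtures
(`preassembledMicelle()`, whose uniform-sphere core has the analytic
$R_g = \sqrt{3/5}\,R$ against which the analysis pipeline is validated).
The fixtures have exact construction guarantees but idealized geometry;
passing them shows the *analysis* is correct, not that the physics of any
particular real formulation is reproduced.

The end-to-end micellization study in the test suite is deliberately scaled
down: 5% P123 in a 21.0 nm box (6,714 beads, 19 chains) instead of the
production 64.25 nm / 192,000-bead systems, integrated for $1.5\times10^6$
steps (45 ns of model time) with two matched-seed runs (water vs. 15%
ethanol). At this scale only trend directions are meaningful — the rise of
$\langle P\rangle_n$ from unimers toward a plateau, the PPO < PEO < solvent
ordering of radial-density peaks, and the suppression of aggregation by
ethanol — never the production-scale aggregation numbers, which would
require orders of magnitude more particles and time. Aggregation kinetics
at fixed concentration do not accelerate in a smaller box (the mean
inter-chain spacing is unchanged), so the plateau reached here is an
early-coarsening quasi-plateau, not the fully equilibrated distribution.

## Known limitations

* No excluded volume beyond the field: chains can overlap; structure below
  the mesh scale is meaningless.
* Stale fields trade momentum conservation between refreshes for speed;
  observables that are sensitive to strict momentum conservation should use
  `updateInterval = 1`.
* The unwrapping strategy assumes aggregates span less than half the box;
  percolating structures (lamellae, bicontinuous phases) are outside the
  intended regime, as are electrostatics, pressure coupling and
  vesicle-vs-micelle classification (the shape descriptors report $Q$, but
  topology detection is left to the user).
* Single-threaded by design; reproducibility is prioritized over speed.
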