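---
title: "Methods: continuum-electrostatics pKa calculations in contpka"
author: "contpka authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: continuum-electrostatics pKa calculations in contpka}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the model,
its assumptions, the tunable parameters, the numerical choices, and the
limits of what the shipped tests demonstrate.

## The physical model

A protein is represented as a rigid set of atomic point charges inside
a low-dielectric region embedded in high-dielectric solvent with mobile
ions.  The electrostatic potential obeys the linearized
Poisson–Boltzmann (LPB) equation,

$$\nabla\cdot[\varepsilon(\mathbf r)\,\nabla\phi(\mathbf r)]
  \;-\; \varepsilon_w\,\kappa^2\,\lambda(\mathbf r)\,\phi(\mathbf r)
  \;=\; -\,4\pi\,C\,\rho(\mathbf r),$$

with $\phi$ in units of $kT/e$, $C = e^2/(4\pi\varepsilon_0 \cdot
1\,\text{Å}\cdot kT)$, $\lambda$ the ion-accessibility indicator and
$\kappa$ the Debye constant ($1/\kappa \approx 9.7$ Å at 100 mM,
300 K).  Linearization is standard for protein titration work: local
potentials can be large, but the salt response is treated in the
weak-field limit.

Titration couples this continuum picture to statistical mechanics over
protonation microstates.  Each titratable group contributes one site
(histidine: two coupled subsites); a site is a pair of charge states
whose difference distribution $\Delta q_i$ drives all of its
electrostatics.  Three ingredients are computed per site:

* **Intrinsic pKa.**  The protonation free energy of the site is
  evaluated in the protein (all other sites in their neutral reference
  states) and in the model compound — the same residue fragment at the
  *same coordinates*, alone in solvent — on *identical grids*.  Their
  difference, converted to pK units, shifts the experimental reference
  constant.  Identical grid placement makes the (large, unphysical)
  grid self-energy cancel exactly; for an isolated model compound the
  two contexts coincide and the reference constant is recovered to
  machine precision, which the tests assert.
* **Interaction matrix.**  $W_{ij}$ is the interaction of site $i$'s
  charge-difference distribution with site $j$'s, in pK units,
  symmetrized by averaging (the residual asymmetry — a pure
  discretization diagnostic — is stored on the fitted object and
  asserted below 0.05 pK in the tests).
* **Microstate energies and sampling.**  The energy model is the
  standard pairwise form over protonation indicators given in the
  README.  Ensembles come from Metropolis Monte Carlo (single-site
  flips plus joint flips for pairs with $|W| > 2$ pK), or from exact
  enumeration up to 20 free sites, which serves as the oracle in the
  test suite.  A site's pKa is the solution of a bias-potential
  titration: bisection on a per-site bias until both states are equally
  populated, every other site re-equilibrated at each step.

## Conventions that the source material left open

* **Sign of the bias.**  "The bias potential at equal populations
  yields the pKa" fixes the magnitude but not the sign convention.  We
  define the bias as *positive when it favors protonation* (it enters
  the energy as $-b_i$ alongside the pH term) and report
  $\mathrm{p}K_a = \mathrm{pH} - b^\ast$.  This is the unique choice
  that recovers $\mathrm{p}K_a = \mathrm{p}K_\text{intr}$ for an
  isolated site, which the single-site closed form verifies in the
  tests.
* **Histidine.**  The two nitrogens are separate sites with reference
  constants 7.0 (Nε) and 6.6 (Nδ) and a +30 pK penalty excluding the
  doubly-deprotonated microstate.  Per-subsite pKa values are
  *microscopic*: during a subsite's titration the sibling nitrogen is
  held protonated.  With the sibling equilibrating instead, the
  exclusion penalty couples the subsites and an isolated imidazole
  would titrate ~0.55 pK below its reference — the reference constants
  already embody the tautomer equilibrium, so building it in twice
  would be double counting.  For the same reason intra-residue subsite
  coupling is excluded from $W$.  Microstate charges for the four
  tautomer states are closed under the linear decomposition
  $q(x_\delta, x_\varepsilon) = q_{00} + x_\delta D_\delta +
  x_\varepsilon D_\varepsilon$.
* **Contribution charges.**  Per-residue contributions use each group's
  *equilibrium-averaged* charges (fractional protonation allowed),
  because a single number per state is wanted; passing `mean_x`
  explicitly to `contribution_table()` gives the fixed-pattern
  alternative.  Under a frozen pattern the decomposition is exactly
  additive (linear response), which both the tests and the acceptance
  script verify.
* **Implicit protons.**  Protonated Asp/Glu carry +0.5 on each
  carboxylate oxygen; deprotonated Arg/Lys spread −1 over their
  titratable protons; deprotonated hydroxyls keep a zero-charge proton
  atom.  The H-bond analysis treats hydrogens with |q| < 0.05 as
  chemically absent so that the graph follows the charge state.

## Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `eps_protein` | 4 | – | standard protein interior (electronic + small nuclear response) |
| `eps_water` | 80 | – | bulk water at 300 K |
| `ionic_strength` | 0.1 | mol/L | physiological screening |
| `temperature` | 300 | K | reference temperature; enters $kT$, $\kappa$, Nernst constant |
| `pH` | 7.0 | – | titration reference point |
| `ion_exclusion` | 2.0 | Å | Stern layer; typical small-ion radius |
| `levels` | 2.5/1.0/0.3 | Å | 3-step focusing; coarsest spans the molecule + 20 Å, finest the site + 10 Å |
| SOR tolerance | 1e-6 | relative update | well below 0.01 pK in derived energies |
| MC schedule | 100 + 10⁴ sweeps | – | single-flip autocorrelation is a few sweeps for these system sizes |
| bias bisection | 0.01 pK | – | an order below the 0.2 pK numerical-error scale of this method class |
| His exclusion | +30 | pK | effectively forbids the imidazolate at any realistic pH |

Atomic radii are PARSE-style element radii (shipped, configurable);
no radius set is canonical for this method class and absolute pKa
values inherit that uncertainty.  Partial charges are CHARMM22-derived
tables (version `contpka-1`); synthetic cofactor groups use uniform
spreading of added charge over their atoms, labeled synthetic.

## Numerical choices

* **Discretization.**  Centered 7-point stencil; edge dielectrics are
  harmonic means weighted by the fraction of each edge inside the van
  der Waals union (5 sample points per edge).  Harmonic weighting is
  the flux-continuous choice and converges fastest at dielectric
  boundaries; the Born-sphere error decreases monotonically through
  1.0/0.5/0.3 Å spacings and is ~0.2% at 0.3 Å (asserted in tests).
* **Boundary condition.**  Debye–Hückel superposition of the source
  charges at the box faces, using the *ambient* dielectric (the solvent
  value, or the uniform value when a uniform-dielectric context is
  requested — using the solvent value there is wrong and was caught by
  the Born oracle during development).  Finer focusing levels take
  boundary values and initial guesses by trilinear interpolation from
  the coarser solution.
* **Solver.**  Red–black SOR with $\omega = 2/(1+\sin(\pi/n))$.
  Deterministic; with `tol = 0` it runs a fixed sweep count, making the
  iteration affine in the source so superposition holds to rounding
  (used by the linearity test).  Non-convergence raises an error with
  the last relative update.
* **Charge spreading and evaluation** are adjoint trilinear operations,
  so energies are consistent and self-terms cancel between matched
  solves.
* **Degenerate inputs.**  Zero charge gives an identically zero field;
  an empty atom set gives uniform solvent; a grid covering no atoms, a
  finer grid leaking outside its parent, non-decreasing levels, or a
  charge on the grid border raise errors rather than warnings.
* **Determinism.**  All Monte Carlo randomness flows through R's RNG
  from explicit seeds (fresh derived seed per bias evaluation); fixture
  generators are seeded; two runs from the same config are
  bit-identical, which the pipeline test asserts.

## Hydrogen placement

Force-field minimization of hydrogen positions is out of scope.
Instead, polar hydrogens are placed at ideal internal coordinates;
rotatable ones (hydroxyls, thiols, ammonium, water) are oriented by an
exhaustive 15° dihedral grid search scored by Coulomb interaction with
provisional charges plus a distance-weighted bonus toward strong
acceptors, followed by one re-scan pass so the network is
self-consistent.  The scan is deterministic and reproduces a geometric
brute-force optimum in the single-acceptor case (tested).  This is an
approximation: compared to minimized hydrogens it can shift absolute
pKa values by up to a few units, which is one reason absolute
reproduction of published full-protein values carries a ±2 pK band
while state-to-state differences are tighter.

## The synthetic generators

`make_model_compound()` builds truncated side-chain fragments (capped
at Cβ).  `make_toy_multisite()` places fragments at controlled
separations and records closed-form Coulomb couplings against the
realized geometry, so the expectation record cannot drift from the
structure.  `make_mini_rc()` builds a ~900-atom bundle emulating the
studied motif: a phenol with two conformers (A "dark" at 4.4 Å
hydroxyl–hydroxyl distance, B "light" at 3.3 Å), a
threonine-like hydroxyl whose rotation cone reaches both the imidazole
nitrogen and the phenolate oxygen, a crystal water, an acidic residue,
and two cofactor rings at unequal distances carrying an optional +1
hole split 2:1.  The low-dielectric interior is a cubic lattice of
neutral carbons (1.9 Å spacing, overlapping van der Waals spheres) with
2.5 Å clearance around the functional groups.

What these fixtures emulate: burial, coupling, conformer dependence,
charge-state-dependent H-bond direction, and the sign structure of
per-residue contributions.  What they do not: real protein packing
heterogeneity, backbone dipoles along folded chains, crystallographic
disorder, or the ~10³ titratable-site scale of a membrane protein
complex.  Green tests on these fixtures therefore validate the
*machinery* (solver, sampling, conventions, decomposition identities),
not the absolute accuracy of any particular protein prediction.

## Problem sizes used in the shipped tests

Test and acceptance runs use focusing levels of 2.5/1.0 Å (0.5 or
0.3 Å finest where an oracle demands it) and grids capped at 81 nodes
per axis; the mini-bundle battery titrates 4 sites over ~900 atoms, and
Monte Carlo oracles run 2×10⁴ sweeps on up to 12-site toys.  These are
the package's chosen demonstration sizes; production runs on full
proteins would use the 2.5/1.0/0.3 Å defaults and the Monte Carlo
path for the hundreds of coupled sites involved.

## Known limitations

* Rigid structures: no conformational sampling coupled to titration;
  conformer dependence is handled by running each conformer as its own
  state and comparing.
* Linear response everywhere: no dielectric saturation, no nonlinear
  PB, no polarizable charges.
* Absolute pKa values depend on the radius set and hydrogen placement;
  state-to-state *differences* are considerably more robust, and the
  reporting (state batteries, contribution deltas) is organized around
  them.
* The mmCIF format is not read; inputs are PDB.
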