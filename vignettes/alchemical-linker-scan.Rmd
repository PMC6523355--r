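---
title: "Ranking prodrug linker lengths by transition-state binding free energy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking prodrug linker lengths by transition-state binding free energy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plafep)
```

## The problem

Phospholipid (PL) prodrugs place a drug moiety on the sn-2 position of a
glycerophospholipid, joined by a chain of CH~2~ units.  Phospholipase A~2~
(PLA~2~), overexpressed in inflamed tissue, hydrolyses the sn-2 ester and
releases the drug — but only when the conjugate can adopt the enzyme's
transition-state geometry, in which the sn-2 carbonyl oxygen coordinates
the active-site calcium.  The linker length N is the design variable: too
short and the bulky drug clashes sterically with the binding-pocket walls;
too long and, in a lipid environment, the extra hydrophobic units
stabilise the *unbound* state, so transfer into the enzyme costs more.

The observable is the hydrolysis rate, proportional to the concentration
of conjugate in the transition-state geometry,

$$K_\mathrm{hydr} \;\propto\; C_\mathrm{tr\,geom} \;\propto\;
  \exp(-\Delta G_\mathrm{tr} / RT),$$

so ranking linker lengths reduces to computing how the transition-state
binding free energy $\Delta G_\mathrm{tr}$ changes with N.  Absolute
binding free energies are out of reach; differences between adjacent
linker lengths are not.  For each pair (N, N−1) a thermodynamic cycle
gives

$$\Delta\Delta G_\mathrm{tr} \;=\; \Delta G^f_\mathrm{mod}
  - \Delta G^i_\mathrm{mod},$$

where $\Delta G_\mathrm{mod}$ is the free energy of converting the
N-conjugate into the (N−1)-conjugate — computed once inside the enzyme
(final state, superscript f) and once as a free molecule in a water or
lipid reference phase (initial state, superscript i).  Telescoping the
pairwise $\Delta\Delta G_\mathrm{tr}$ values yields a relative
$\Delta G_\mathrm{tr}$ profile over N = 2..8, anchored at N = 6.

## The two-step transformation

Each $\Delta G_\mathrm{mod}$ is computed in two steps.

**Step 1 — alchemical removal (TI).**  The terminal CH~2~ bead is
decoupled through the polynomial mixing Hamiltonian

$$V(\lambda) = (1-\lambda)^k\, V_N + \left[1-(1-\lambda)^k\right] V_{N-1},
  \qquad k = 4,$$

and the free energy follows from thermodynamic integration,
$\Delta A = \int_0^1 \langle \partial V/\partial\lambda\rangle_\lambda\,
d\lambda$, evaluated by 9-node Gauss–Legendre quadrature.  Gauss–Legendre
is used because its interior nodes never require sampling exactly at the
end states.  In the decoupled state the vanished bead keeps only its
chain bond (an environment-independent tether whose constant free-energy
contribution cancels in every cycle difference) and loses its angle and
all nonbonded terms; because the nonbonded repulsion is capped at full
overlap, $\langle\partial V/\partial\lambda\rangle$ stays finite
everywhere.  During the transformation the drug is held near the *new*
linker end by the same soft harmonic bond used in step 2, at the distance
it naturally has before removal (2 Å for one unit, 3.5 Å for the two-unit
closure check, snapped to the umbrella grid).  Holding the drug at its
natural distance keeps the alchemical perturbation small; an early design
that parked the drug at the 5 Å plateau during TI was several-fold
noisier for the same cost.

**Step 2 — re-attachment (umbrella sampling + WHAM).**  The drug is
connected to the linker end by a harmonic bond of force constant
4.0 kcal mol^−1^ Å^−2^ whose *equilibrium distance is the umbrella
variable*: windows move it from 0.5 Å to 5 Å and back in 0.5 Å steps,
each window seeded from its predecessor's final frame (sweep continuity —
this is what makes the forward/backward discrepancy a meaningful
sampling-error proxy).  The weighted histogram analysis method (WHAM)
unbiases the pooled histograms into a potential of mean force (PMF),
gauge-fixed to zero at its minimum, and into per-window free energies
$f_j$ (gauge $f_1=0$).

Two readings of the attachment free energy are reported:

* `delta_G_attach` — the PMF endpoint difference, profile(0.5 Å) −
  profile(5 Å).  This is the conventional way to read a PMF, and the
  headline number in `attachment_free_energy()`.
* `delta_G_attach_windows` — $f(d_0{=}0.5) - f(d_0{=}\text{detach})$, the
  free-energy difference between the restrained *window ensembles*
  themselves (a Boltzmann-integrated reading of the profile).

The cycle assembler composes legs from the second reading.  The reason is
exactness of composition: the TI end state *is* the detach-window
ensemble, so `delta_A + f(attach) − f(detach)` telescopes without any
residual, whereas a PMF point value and a restrained ensemble differ by
an $O(RT)$ term wherever the underlying landscape is curved on the scale
of the restraint width (≈0.4 Å at k = 4).  The cycle-closure test (direct
two-unit removal versus two telescoped one-unit legs) passes within
statistical error only with the ensemble-consistent reading; with
endpoint differences it would inherit one such residual per leg.
Hysteresis errors are computed for both readings as half the
forward-minus-backward difference.

## The coarse-grained model

One bead per CH~2~ unit, one bead for the drug moiety (radius 2.5 Å —
bulky, the source of the steric mechanism), three headgroup beads, four
sn-1 tail beads, and an sn-2 carbonyl bead.  Bonds are harmonic
(k = 100 kcal mol^−1^ Å^−2^, r~0~ = 1.5 Å), chain angles weakly harmonic
(2 kcal mol^−1^ rad^−2^, straight), and nonbonded pairs (beyond three
bonds) repel through a capped soft sphere
$U = A\,(1-(r/\sigma)^2)^2$ for $r<\sigma$, which is finite at full
overlap — the property the alchemical end states need.  Units are Å, ps,
amu and kcal/mol throughout; R = 1.987204×10^−3^ kcal mol^−1^ K^−1^;
temperature defaults to 298.15 K.

Three environments stand in for the three thermodynamic states:

* **Transition-state pocket** (`ts_pocket`): a calcium-like Gaussian
  attraction acting on the carbonyl bead (depth 8 kcal/mol, width 1 Å)
  plus a harmonic restraint (10 kcal mol^−1^ Å^−2^, r~0~ = 0) tying the
  carbonyl to the anchor — the transition-state geometry surrogate, kept
  as a differentiable restraint rather than a rigid constraint — and
  repulsive wall spheres.  The packaged `clash_pocket_A` fixture arranges
  the walls as six-sphere rings forming a funnel that narrows toward the
  anchor (ring offsets 3.8/3.1/3.2/3.9/3.9/4.3 Å at
  x = 0.8/2/3.5/5/6.5/8 Å along the channel): a drug bead attached at
  the end of a 2-unit linker sits deep in the narrow section and overlaps
  the walls by ≈10 kcal/mol, a 4-unit attachment by ≈2, and a 6-unit
  attachment is clear.  The mouth ring matters: without it the chain
  simply bends out of the channel and the designed clash never appears in
  the free energy.  `clash_pocket_B` is a slightly wider, softer variant
  standing in for a second enzyme; no structural fidelity to bee-venom or
  human PLA~2~ is claimed for either.  `pocket_from_pdb()` can build the
  same kind of model from any real PDB structure (one wall sphere per
  selected C~α~, anchor at the calcium HETATM).
* **Water reference**: no external terms (implicit solvent).
* **Lipid reference**: a flat-bottom slab on |z| (half-width 8 Å,
  2 kcal mol^−1^ Å^−2^ outside) confining tail and linker beads, plus a
  smooth solvation well of −0.8 kcal/mol per tail/linker bead inside the
  slab.  The 0.8 kcal/mol is the classic hydrophobic transfer free energy
  per CH~2~ between water and a hydrocarbon phase; it is what makes
  removing a CH~2~ unit *cost* free energy in the lipid phase and hence
  raises the transition-state transfer free energy of the longest
  linkers — the lipid-specific trend the method is designed to expose.

## Sampling and estimation choices

* **Integrator**: BAOAB-split Langevin dynamics, timestep 0.002 ps.  The
  generic protocol default friction is 1 ps^−1^; production stages (TI
  nodes, umbrella windows) use 10 ps^−1^, the implicit-solvent value,
  which is also near critical damping for the soft attachment coordinate
  and decorrelates it fastest.  Single-bead oracle checks use 8 ps^−1^
  for the same reason.  In C++ (Rcpp) — an MD inner loop in interpreted R
  would not reach these problem sizes.
* **Constraints**: holonomic pair-distance constraints are available via
  SHAKE-style post-step projection (tolerance 10^−6^ Å) with velocity
  projection; the production pipeline uses restraints instead (see
  above), so constraints are exercised by the engine tests.
* **Error bars**: block averaging with doubling block sizes until the
  standard-error estimate plateaus (±10% over two doublings) or fewer
  than 8 blocks remain — the plateau value corrects the naive standard
  error for serial correlation.  TI errors propagate through the
  quadrature weights; umbrella errors are forward/backward hysteresis;
  cycle errors combine the two in quadrature, treating them as
  independent.
* **Problem sizes**: 10^5^ steps per λ node (×9 nodes) and 6×10^4^ steps
  per umbrella window (×20 windows), with the first 20% of each stage
  discarded as equilibration and samples recorded every 10 (TI) or 5
  (umbrella) steps.  These desk-scale sizes resolve the designed
  free-energy differences (≈1–5 kcal/mol) with telescoped uncertainties
  of ≈0.2–0.3 kcal/mol; all lengths are configurable up to the published
  200 ps / 2 ns scales.
* **WHAM**: 0.1 Å bins, convergence when max |Δf~j~| < 10^−6^ kcal/mol
  (≤10^5^ iterations), log-space accumulation, zero-count bins excluded
  from the profile rather than interpolated.
* **Randomness**: one root seed; every stage (λ node, window, scan leg)
  derives its own stream via a documented label-fold rule
  (`derive_seed()`), so stages are reproducible independently and
  re-running a cached scan is bit-identical.
* **Gauge choices**: the scan anchors the relative profile at N~0~ = 6
  and reports rates as ratios to that anchor; rates depend only on
  differences, so any other anchor shifts nothing observable.

## What the synthetic systems do and do not show

The fixtures emulate the *statistical structure* the estimators assume: a
confining pocket with an attractive anchor and steric walls that clash
with the drug bead at short linker lengths, reference phases that differ
only in how they solvate CH~2~ units, smooth landscapes with barriers of
a few kcal/mol, and overlapping biased windows.  Passing tests therefore
demonstrate that the two-step estimator is *consistent* (cycle closure,
null-cycle cancellation, quadrature convergence, analytic-landscape
recovery) and that the designed steric and hydrophobic mechanisms map to
the expected rank order of linker lengths.  They do not demonstrate
anything about real PLA~2~ energetics: the pocket is a cartoon, water and
lipid are implicit, there are no electrostatics beyond the anchor term,
and the drug is a single sphere.  Conclusions about a real conjugate
would require the same protocol on atomistic systems.

## Degenerate inputs and numerical corner cases

Zero-temperature protocols are accepted as the quench limit (the O-step
noise vanishes).  Window schedules whose span is not divisible by the
spacing snap to the nearest grid with a warning; a zero-span schedule
degenerates to a single window.  Windows without mutual histogram
overlap raise a disconnected-histogram error naming the gap.  If a
strongly repulsive pocket pushes every sample away from the 0.5 Å grid
minimum, the PMF endpoint reading is reported as `NA` while the
window-ensemble reading (which only needs the window to have run)
remains defined; requesting a distance outside both is a coverage error.
Energies above 10^6^ kcal/mol abort with advice to reduce the timestep.

## Known limitations

Single reaction coordinate only (the attachment distance); no replica
exchange or MBAR-style multistate reweighting (TI is the published
estimator; MBAR would be an extension); hysteresis is a proxy, not a
rigorous error bound; the lipid slab is aperiodic and has no explicit
bilayer structure; `shorten_linker()` rebuilds rather than edits
topologies, so bead identity across companions is by label.

## A worked mini-example

A two-length scan in water only, at reduced sampling (seconds, not
minutes):

```{r mini-scan, eval = FALSE}
cfg <- scan_config(linkers = 3:4, references = "water", anchor_linker = 4,
                   ti_steps = 10000, us_steps = 8000, seed = 1)
scan <- run_linker_scan(cfg)
tidy(scan)
glance(scan)
autoplot(scan)
```

The full study conditions are simply `scan_config(seed = ...)`: linkers
2–8, water and lipid references, `clash_pocket_A`, anchor N~0~ = 6.
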