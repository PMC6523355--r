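# plafep

Coarse-grained alchemical free-energy scans for phospholipid-prodrug
linker design.

## The scientific problem

Phospholipid (PL) prodrugs carry a drug moiety on the sn-2 position of a
glycerophospholipid, joined by a chain of N CH2 units. Phospholipase A2
(PLA2) — overexpressed in inflamed tissue, e.g. the colonic mucosa in
ulcerative colitis — cleaves the sn-2 ester and releases the drug, but
only when the conjugate fits the enzyme's transition-state geometry
(carbonyl oxygen coordinated to the active-site calcium). The linker
length controls that fit: short linkers clash sterically with the pocket
walls; in a lipid environment, long linkers are hydrophobically
stabilised in the *unbound* state. The hydrolysis rate follows the
transition-state binding free energy,

    K_hydr ∝ C_tr-geom ∝ exp(−ΔG_tr / RT),

so the design question "which N is activated fastest?" becomes "how does
ΔG_tr depend on N?". `plafep` answers it with relative free energies
from a thermodynamic cycle: for each adjacent pair (N, N−1),

    ΔΔG_tr = ΔG_mod^f − ΔG_mod^i,

where ΔG_mod is the free energy of shortening the linker by one unit,
computed once in the enzyme pocket (f) and once as a free molecule in a
water or lipid reference phase (i). Each ΔG_mod is computed in two
steps, following the published protocol:

1. **Thermodynamic integration** over the mixing Hamiltonian
   `V(λ) = (1−λ)^k V_N + [1−(1−λ)^k] V_{N−1}` with k = 4, integrating
   ⟨∂V/∂λ⟩ over 9 Gauss–Legendre nodes, with the drug moiety held near
   the new linker end;
2. **Umbrella sampling + WHAM** for re-attaching the drug: the
   equilibrium distance of the connecting bond (4.0 kcal/mol/Å²) sweeps
   0.5 → 5 → 0.5 Å in 0.5 Å steps, and the forward/backward discrepancy
   (hysteresis) is the sampling-error proxy.

Pairwise ΔΔG_tr values telescope into a relative ΔG_tr profile over
N = 2–8 (anchored at N = 6) and, through the Boltzmann map, into
relative hydrolysis rates. Everything runs at desk scale on
coarse-grained surrogate systems: a BAOAB Langevin engine (Rcpp), capped
soft-sphere repulsion so alchemical end states stay finite, a synthetic
funnel-shaped "clash pocket" with a calcium-like anchor, and implicit
water/lipid reference phases. The methods vignette
(`vignettes/alchemical-linker-scan.Rmd`) documents the model, every
tunable parameter, and the estimator design choices.

## A worked example

A reduced two-pair scan in the water reference (seconds; the full study
conditions are `scan_config(seed = ...)` — linkers 2–8, water + lipid,
about 3 minutes on one CPU):

```r
library(plafep)
cfg <- scan_config(linkers = 4:6, references = "water", anchor_linker = 6,
                   ti_steps = 20000, us_steps = 16000, seed = 1)
scan <- run_linker_scan(cfg)
tidy(scan)
#> # A tibble: 3 × 5
#>   reference     N rel_G_tr error rel_rate
#>   <chr>     <int>    <dbl> <dbl>    <dbl>
#> 1 water         4    0.928 0.304    0.209
#> 2 water         5    0.216 0.229    0.695
#> 3 water         6    0     0        1
glance(scan)
#> # A tibble: 1 × 4
#>   reference optimal_linker spread_kcal_mol incomplete
#>   <chr>              <int>           <dbl> <lgl>
#> 1 water                  6           0.928 FALSE
```

Reading: shortening the linker from 6 to 4 units raises the
transition-state binding free energy by ~0.9 kcal/mol (the drug bead
begins to overlap the pocket walls), which the rate map turns into a
~5-fold slower hydrolysis for N = 4 relative to N = 6 — the onset of the
short-linker penalty, which grows to ~5 kcal/mol by N = 2 in the full
scan. `rel_G_tr` is relative to the N = 6 anchor (kcal/mol), `error`
combines TI block errors and umbrella hysteresis in quadrature, and
`rel_rate = exp(−rel_G_tr/RT)`. `autoplot(scan)` draws the profile;
lower-level results (`run_ti()`, `solve_wham()`,
`attachment_free_energy()`, `linker_leg()`) all have `tidy()`/`glance()`
/`autoplot()` methods.

A thin command-line front end is installed at `inst/cli/plafep.R`
(subcommands `build`, `ti`, `umbrella`, `wham`, `cycle`, `scan`,
`validate`, `fixtures`), reading the YAML configuration documented in
`load_config()`.

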