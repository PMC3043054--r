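# ionshells

Shell-resolved ion–protein encounter kinetics from molecular dynamics
trajectories.

Before a Ca²⁺ ion reaches a specific binding site on an EF-hand protein such
as Calbindin D9k, it is detained in discrete solvation shells above the
protein surface, where its diffusion coefficient drops, its residence time
grows, and it can skim laterally from residue to residue ("antenna effect")
instead of returning to the bulk between contacts. `ionshells` is an R
package for quantifying that search phase from MD trajectories — and for
validating every estimator on seeded synthetic data with exact ground truth.

## What it computes

For a trajectory with one protein and tracked cation(s):

* **Distance and shells** — per-frame minimum-image distance to the nearest
  (heavy) protein atom; assignment to solvation shells
  (`[0, 0.35)`, `[0.35, 0.60)`, … `[1.85, 2.10)` nm, bulk beyond);
  occupancy histograms within 1.2 nm.
* **Residence kinetics** — residence events per shell with a 2 ps
  short-excursion grace rule; survival curves `N(t) = #{events ≥ t}`;
  single/bi-exponential fits by Levenberg–Marquardt on points with counts
  above 10, `N(t) ≈ A₁e^{−t/τ₁} + A₂e^{−t/τ₂}` (τ₁ < τ₂), with the relative
  RMS error as fit quality; mean residence split by exit direction
  (inward/outward).
* **Diffusion** — time-origin-averaged MSD (optionally restricted to
  in-shell segments pooled over an ensemble), `D = slope/6` on a 10–100 ps
  lag window with a linearity diagnostic; per-event surface mobility as the
  maximum squared displacement from the event entry point in the
  Kabsch-superposed protein frame, summarised as exceedance curves.
* **Encounters** — ion–residue (or per-oxygen, carboxylate-merged) contact
  intervals; classification into **primary** (arrival from bulk) and
  **secondary** (transfer from another residue without leaving the first
  shell) encounters; binding-time tables, inter-residue transfer counts,
  secondary/primary ratios, encounter intervals, contact concurrency and
  free fraction.
* **Rates** — Debye length, Debye–Smoluchowski association rate
  `k = 4π(D₁+D₂)R_eff N_A 10⁻³` with a screened-Coulomb effective radius
  `1/R_eff = ∫_R^∞ e^{U(r)/k_BT}r^{−2}dr`, and pseudo-first-order encounter
  rates/intervals at a given concentration.
* **Synthetic truth** — seeded generators (free Brownian ion, two-exponential
  residence mixtures, Langevin ion around a decorated sphere, Markov
  surface-hopping chains) that emit exact ledgers against which every
  pipeline stage is tested.

Inputs: PDB/GRO topologies, DCD trajectories (via bio3d), or the package's
plain-text internal trajectory format; per-shell residence constants and a
per-residue encounter table ship as plain-text fixtures under
`inst/extdata/`.

## Worked example

Recover the second-shell residence constants from synthetic data, pool the
packaged encounter table, and compute the worked rate example:

```r
library(ionshells)

g   <- gen_residence_durations(3.611, 212.193, weight_fast = 0.5,
                               n = 1e5, seed = 42)
fit <- fit_exponential(survival_curve(g$durations, dt = 1), order = 2)
fit
#> Exponential residence-decay fit (order 2)
#>   component 1: A = 49720, tau = 3.598 ps
#>   component 2: A = 50341, tau = 211.2 ps
#>   relative RMS error: 0.001818 on 1754 points (N > 10 )
```

The generator drew 10⁵ durations half-and-half from exponentials with means
3.611 and 212.193 ps; the bi-exponential survival fit returns both time
constants to well under 1%, with amplitudes near the true 50/50 split.

```r
summarize_encounter_table(load_encounter_table(), total_time_ns = 2000)
#> Pooled table: 1543 primary, 457 secondary; secondary/primary = 0.296
#>   mean primary interval:   1.296 ns
#>   mean secondary interval: 4.376 ns
```

Pooling both protein variants of the packaged table: roughly one contact in
four is reached by surface transfer rather than from the bulk, primary
encounters arrive every ≈ 1.3 ns at this ion concentration, secondary ones
every ≈ 4.4 ns.

```r
pseudo_first_order(3e10, 0.025)
#> $rate
#> [1] 7.5e+08
#>
#> $mean_interval_ns
#> [1] 1.333333
```

A diffusion-limited rate of 3×10¹⁰ M⁻¹s⁻¹ at 25 mM gives an apparent rate
of ≈ 0.8×10⁹ s⁻¹ — one encounter every ≈ 1.3 ns, consistent with the
primary-encounter interval read off the table above.

`run_pipeline()` chains all stages (distance → shells → residence →
diffusion → encounters → kinetics) on an internal-format or generated
trajectory and writes deterministic CSV/JSON tables plus a reproducibility
manifest; see the methods vignette (`vignettes/ionshells-methods.Rmd`) for
the models, conventions and design decisions.

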