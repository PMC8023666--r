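# torsionbo

Active-learning conformer search over torsion space, in R.

Finding the low-energy conformers of a flexible molecule means locating
the minima of its potential energy surface (PES) as a function of the
dihedral angles d<sub>1</sub>…d<sub>N</sub> about its rotatable bonds —
a multi-well, periodic, expensive-to-evaluate landscape where exhaustive
grids are unaffordable whenever each energy is a quantum-chemistry
single point. `torsionbo` is for computational chemists and
structural-modelling researchers who want that search to be
sample-efficient, automated and reproducible.

The core loop is Bayesian optimization with a Gaussian-process
surrogate:

* GP regression with a product of periodic (exp-sine-squared) kernels,
  period fixed at 360° per dimension, hyperparameters fitted by
  marginal-likelihood maximization;
* acquisition by the exploratory lower confidence bound,
  eLCB(x) = μ(x) − √β<sub>t</sub> σ(x), with the schedule
  β<sub>t</sub> = 2 log(t<sup>N/2+2</sup>π²/(3δ));
* an energy transform E<sub>new</sub> = E<sub>cut</sub> + log₁₀E
  (relative energies above E<sub>cut</sub> = 2 eV) that damps
  steric-clash spikes instead of masking the search space;
* multi-start L-BFGS extraction of **all** local minima of the learned
  surrogate, with periodic duplicate purging;
* refinement into a staged hierarchy: relaxation (fmax = 0.01 eV/Å) →
  +ZPE → +F<sub>vib</sub>(300 K) from a finite-difference harmonic
  Hessian (δ = 0.0025 Å) → optional high-level single-point deltas
  ΔCC = E<sub>high</sub> − E<sub>opt</sub>;
* windowed convergence monitoring of the predicted global minimum
  (ΔE < 0.025 eV, Δd < 10°) and energy-vs-conformer-index curves for
  the low-energy spectrum.

Energy backends plug in behind a calculator interface: analytic
multi-well torsional surfaces (exactly enumerable by grid scan — the
package's test fixtures), a simple bonded molecular-mechanics force
field, and a file-exchange bridge for coupling to external
quantum-chemistry codes. The methods vignette
(`vignettes/conformer-search-methods.Rmd`) documents the model,
defaults and design choices in detail.

## Worked example

Search a seeded 2D analytic surface (7 grid-enumerated wells), extract
and purge its minima, polish them on the true potential and rank:

```r
library(torsionbo)

pes <- generate_test_pes(dimension = 2, seed = 7, minima_range = c(3, 8))
sr  <- run_search(pes, search_config(budget = 150, seed = 11))
print(sr)
#> search_result: 150 evaluations in 2D; best E -0.259669 eV; converged at 27; 0% damped acquisitions

cand    <- purge_duplicates(extract_minima(sr$gp))
refined <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
  r <- relax_torsions(pes, as.numeric(cand[i, c("d1", "d2")]))
  data.frame(d1 = r$torsions[1], d2 = r$torsions[2], E_opt = r$energy)
}))
refined$label <- sprintf("c%03d", rank(refined$E_opt))
print(assemble_hierarchy(refined))
#> conformer_hierarchy: 7 conformer(s); stages: opt
#>  label    rel_opt
#>   c001 0.00000000
#>   c002 0.00165050
#>   c003 0.01461104
#>   c004 0.02381369
#>   c005 0.10287086
#>   c006 0.13732988
#>   c007 0.16442460
```

150 energy evaluations recover all 7 wells of the brute-force 1°
reference scan (129 600 evaluations) to within a degree; the predicted
global minimum stabilized (energy within 0.025 eV, dihedrals within
10°, over a 10-iteration window) at iteration 27. `rel_opt` is each
conformer's energy in eV above the most stable one after polishing; for
molecule-backed calculators the same `assemble_hierarchy()` output
carries the further `+VE(0 K)`, `+VE(300 K)` and `+ΔCC` columns.

The same run is available declaratively:

```r
run_pipeline(system.file("extdata", "example_analytic.yaml", package = "torsionbo"))
```

which writes `trace.csv`, `minima.csv`, `hierarchy.csv/json` and a
reproducible `manifest.json`. A molecular example with full relaxation
and vibrational corrections (hydrogen peroxide on the built-in force
field) is in `inst/extdata/example_mm.yaml`, and
`inst/cli/torsionbo.R` exposes the stages as shell subcommands
(`search`, `minima`, `refine`, `rank`, `map`, `makepes`).

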