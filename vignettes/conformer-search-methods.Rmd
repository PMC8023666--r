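---
title: "Conformer search by Bayesian optimization over torsion space: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformer search by Bayesian optimization over torsion space: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A conformer is a stable conformation of a molecule, a local minimum of its
potential energy surface (PES). For a molecule with rotatable single
bonds the conformational space is dominated by the dihedral (torsion)
angles $d_1, \dots, d_N$ about those bonds, and the standard
*building-block approximation* freezes all bond lengths and bond angles
at optimized reference values and searches only in torsion space. Even
so, an exhaustive grid is hopeless: at 30 points per dimension a 5D scan
costs $30^5 \approx 2.4\times10^7$ energy evaluations, each of which
would be a quantum-chemistry single point in a production setting.

torsionbo implements an active-learning alternative: a Gaussian-process
(GP) surrogate of the torsional PES is refined by Bayesian optimization
(BO), each iteration spending exactly one true energy evaluation where
the surrogate is both promising and uncertain. The learned surrogate is
then mined for *all* of its local minima, and the resulting candidate
conformers are refined by relaxation, harmonic vibrational free-energy
corrections, and optional high-level single-point deltas into a staged
energy hierarchy.

The quantum-chemistry backend is deliberately out of scope: energies
enter through a calculator interface, and the package ships analytic
torsional surfaces, a small molecular-mechanics force field and a
file-exchange bridge so that every stage is testable and reproducible on
a desk.

## The surrogate model

Each observation is a pair (torsion vector $\mathbf d$ in degrees,
energy $E$ in eV). The GP prior uses a constant mean (the sample mean)
and a product of exp-sine-squared periodic kernels,

$$k(\mathbf x, \mathbf y) = \sigma_f^2 \prod_{j=1}^{N}
  \exp\!\left(-\frac{2\sin^2\big(\pi (x_j - y_j)/360\big)}{s_j^2}\right),
  \qquad s_j = \frac{2\pi \ell_j}{360},$$

with the period fixed at 360° in every dimension — torsions live on a
torus, and the kernel makes every prediction exactly 360°-periodic by
construction. The parameterization maps $\ell_j$ to an interpretable
lengthscale in degrees: for separations much smaller than the period the
kernel reduces to $\exp(-\Delta^2/2\ell_j^2)$.

Hyperparameters ($\ell_j$, signal sd $\sigma_f$) are fitted by
maximizing the log marginal likelihood with L-BFGS-B from a fixed
multi-start schedule: three cold starts ($\ell_0 \in \{40, 90, 160\}°$)
on the first fit of a search, and afterwards a warm start from the
previous fit plus one mid-range cold start. Lengthscales are bounded to
$[5°, 720°]$. The observation-noise variance is fixed at $(10^{-4}\,
\mathrm{eV})^2$: the supported backends are deterministic, so the floor
is purely numerical. Cholesky failures trigger jitter escalation
($10^{-10} \to 10^{-8} \to 10^{-6}$ relative to $\sigma_f^2$) before a
conditioning error is raised. Everything is deterministic given the run
seed, and fits are reproducible.

The posterior mean is the current best PES estimate and its analytic
gradient (also implemented, and checked against central differences) is
what makes the post-processing cheap.

## The acquisition loop

The search starts from a Latin-hypercube design of
$n_0 = \max(5, 2N)$ points over $[-180, 180)^N$. A low-discrepancy
space-filling design is the standard BO initialization; the Latin
hypercube generator (`lhs`) was chosen as the package's design primitive
and is driven by the run seed. Iteration counts reported by the package
*include* these initial evaluations.

Each subsequent point minimizes the exploratory lower confidence bound

$$\mathrm{eLCB}(\mathbf x) = \mu(\mathbf x) - \sqrt{\beta_t}\,
  \sigma(\mathbf x), \qquad
  \beta_t = 2\log\!\big(t^{N/2+2}\pi^2 / (3\delta)\big),\ \delta = 0.1,$$

a standard LCB schedule whose exploration weight grows slowly with the
iteration $t$ and dimension $N$. The acquisition is minimized by
multi-start L-BFGS (best observed sample plus 7 uniform random starts);
because the kernel is periodic the optimization is unconstrained and the
result is wrapped back into $[-180, 180)$. Ties between symmetric minima
are resolved by whichever start converged lowest — stable under a fixed
seed.

### Energy transform

Unrestricted torsion sampling occasionally builds sterically clashing
geometries whose enormous energies would wreck the GP fit. Rather than
masking the search space, energies are damped: observations are first
shifted to be relative to the current lowest observation (so the scale
is positive and offset-free), and any relative energy above a cutoff
$E_\mathrm{cut}$ is replaced by

$$E_\mathrm{new} = E_\mathrm{cut} + \log_{10} E .$$

$E_\mathrm{cut} = 2$ eV is the default. As printed this mapping has a
step of $\log_{10} E_\mathrm{cut}$ at the cutoff; the step variant is
the default behaviour, and a continuous variant (subtracting
$\log_{10} E_\mathrm{cut}$ on the damped branch) is available behind
`continuous_transform = TRUE` for users who prefer a seamless join. The
GP is always fitted to transformed energies; raw energies are kept for
reporting, and the fraction of damped acquisitions is part of the search
result. Failed evaluations (non-finite backend output) are assigned a
relative energy far above the cutoff, damped accordingly and flagged,
so a single backend failure cannot abort a long run.

### Convergence

The predicted global minimum (multi-start minimization of the posterior
mean) is tracked at every iteration. The search is declared converged at
the first iteration $i$ such that over a window of `window` iterations
(default 10) ending at $i$ the predicted minimum energy varies by less
than 0.025 eV and each predicted dihedral by less than 10° (periodic
distance). These thresholds are the package defaults for "negligible
change" in a converged search. Because near-degenerate wells can swap
the *global* minimum between iterations indefinitely (a real feature of
multi-well landscapes, not a bug), convergence of the low-energy
spectrum is additionally monitored with the energy-versus-conformer-index
curves of `energy_vs_index_curve()`: once consecutive budgets agree
below an energy ceiling (default 0.25 eV), the low-energy minima are
converged even if their order keeps shuffling. For the index curves the
deviation between budgets is computed on per-budget min-referenced
energies, and each budget's global-minimum offset against a reference
budget is reported separately; a non-zero offset is exactly the "curve
does not start at zero" signature of a premature budget.

## Mining the surrogate for conformers

All local minima of the posterior mean are located by L-BFGS
minimizations started from every acquisition location (models built from
more data have more basins, so dense starts are the point, and the
surrogate is cheap). A terminus qualifies as a minimum when the
posterior-mean gradient norm is below $10^{-4}$ eV/degree;
non-converged starts are counted and dropped. Since many starts fall
into the same basin, duplicates are purged by greedy clustering in
ascending energy order: a candidate joins an earlier representative when
every dihedral is within `d_tol` (periodic) *and* the energies are
within `e_tol`. Defaults `d_tol = 15°`, `e_tol = 0.01` eV merge
numerical jitter while keeping chemically distinct rotamers (gauche vs
anti differ by ~120°) well separated; the final, application-specific
pruning is left to the user. The procedure keeps the deepest
representative, is order-deterministic and idempotent.

## Refinement and the energy hierarchy

Surrogate minima inherit the rigid-geometry approximation, so candidate
conformers are refined in stages, each stage re-zeroed at its own most
stable structure:

1. **search** — the surrogate prediction at the extracted minimum.
2. **opt** — energy after relaxation. For molecule-backed calculators
   all Cartesian degrees of freedom are freed and relaxed by L-BFGS
   until the maximum per-atom force norm is below `fmax` (default 0.01
   eV/Å, step limit 500); for the analytic backend the true potential is
   minimized in torsion coordinates.
3. **+VE(0 K)** — adds the zero-point energy
   $\sum_i \hbar\omega_i / 2$.
4. **+VE(300 K)** — adds the full harmonic vibrational free energy
   $$F_\mathrm{vib}(T) = \sum_i \left[\tfrac{\hbar\omega_i}{2} +
     k_B T \ln\!\big(1 - e^{-\hbar\omega_i / k_B T}\big)\right],$$
   the discrete-mode form of the phonon-density-of-states integral (a
   molecule's DOS is a sum of delta functions). $F_\mathrm{vib}(0)$
   equals the ZPE by construction, and the ZPE and thermal terms are
   reported separately. 300 K is the default because most reference
   experiments are done at room temperature.
5. **+ΔCC** — adds a high-level single-point delta
   $\Delta = E_\mathrm{high} - E_\mathrm{opt}$ (e.g. coupled-cluster
   minus the relaxation level), ingested from a two-column label/energy
   CSV. Typically only the lowest conformers get one; records without a
   delta are excluded from this stage.

Frequencies come from a central finite-difference Hessian of the forces
(displacement $\delta = 0.0025$ Å), symmetrized and mass-weighted.
Rigid-body translations and rotations are removed by projecting out the
six (five for linear molecules) Eckart-style vectors before
diagonalization — more robust than discarding the six smallest modes
when low torsional frequencies approach zero. Eigenvalues whose
magnitude falls below the 10 cm$^{-1}$ equivalent are treated as
numerical zeros; more negative ones are imaginary modes, which are
flagged and excluded from $F_\mathrm{vib}$. Constants: $k_B =
8.617333\times10^{-5}$ eV/K; the $\hbar\omega$ conversion is computed
from CODATA values.

Ranks are assigned per stage in ascending relative energy with ties
broken lexicographically by label, so hierarchy assembly is invariant
under input order.

## Synthetic surfaces: what they do and do not emulate

`generate_test_pes()` draws cosine series up to order 3 per dimension
(amplitudes 0.02–0.12 eV with random signs and phases) plus optional
pairwise difference couplings ($|c_{ij}| \le 0.03$ eV),

$$E(\mathbf d) = \sum_j \sum_{k=1}^3 a_{jk}\cos(k\theta_j + \phi_{jk})
  + \sum_{i<j} c_{ij}\cos(\theta_i - \theta_j),$$

and redraws (up to 50 times) until a brute-force grid scan finds a
requested number of local minima. Orders 1–3 reproduce the 1-, 2- and
3-fold barriers of real single-bond torsional profiles, and the
amplitude range yields wells and barriers of a few tenths of an eV —
the scale seen in amino-acid torsional maps. The scan resolution is 1°
for 1–2 torsions and 5° for 3–4; above that the generator accepts a
coarser, documented grid. `cysteine_d1_profile()` is a fixed
three-well 1D instance of the same family: a dominant 3-fold rotor term
with 1- and 2-fold components that break the well degeneracy, emulating
a single side-chain dihedral of an amino acid.

These fixtures share the true PES's periodicity, smoothness and
multi-well topology, so they exercise the search, extraction, purging
and torsion-space relaxation machinery exactly. They do **not** emulate
steric-clash energy spikes (couplings are gentle), anharmonic
bond/angle coupling to the torsions, or the cost profile of a real
backend — so a passing test suite demonstrates the correctness of the
algorithmic machinery, not chemical accuracy for any particular
molecule. The bundled hydrogen peroxide example (an idealized, synthetic
geometry, not an optimized one) plus the simple bonded force field add
the missing Cartesian ingredients — relaxation that actually moves bond
lengths and angles, and a vibrational analysis with physical units — at
toy-model fidelity.

## Numerical choices and degenerate inputs

* Angles are degrees everywhere, canonical half-open interval
  $[-180, 180)$; wrapping is idempotent and $+180$ maps to $-180$.
* Dihedral sign follows the IUPAC right-hand convention (sighting from
  the second to the third atom); the implementation is cross-checked in
  the tests against an independent structural-bioinformatics package.
* Rotating a searchable bond moves the connected component on its far
  side; a bond inside a ring has no such split and is rejected as
  non-rotatable at model construction.
* Collinear atom triplets make a dihedral undefined and raise a
  degenerate-geometry error rather than returning garbage.
* Connectivity may be given explicitly or derived from covalent radii
  (cutoff 1.2 × the radius sum); an explicit bond list always wins,
  since auto-derivation is ambiguous for unusual geometries.
* A budget equal to the initial design size degenerates gracefully: the
  surrogate is fitted once and the pipeline completes on the initial
  samples only.
* Problem sizes in the shipped tests and validation script were chosen
  to exercise every code path at desk scale: 1D runs use budgets of
  12–30 evaluations, the 2D end-to-end fixture uses 150 evaluations
  (its 7 grid-enumerated wells are all recovered), and vibrational
  checks use 1–4 atom systems with closed-form spectra.

## Known limitations

* Full GP inference is $O(n^3)$; past a few thousand samples the loop
  slows markedly (hyperparameters are refitted every 10th iteration
  beyond 200 samples to postpone this). Sparse approximations are out
  of scope.
* Ring puckering, bond/angle sampling and symmetry detection are out of
  scope; the search coordinates are exactly the user-declared rotatable
  dihedrals.
* The harmonic approximation ignores anharmonicity and
  rotational/translational partition functions; hierarchies at elevated
  temperatures inherit those limits.
* The duplicate-purge thresholds are heuristics. With `d_tol` larger
  than the distance between genuinely distinct shallow wells, basins
  merge; the defaults err on the side of keeping structures.
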