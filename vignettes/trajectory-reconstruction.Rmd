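---
title: "Invariants and slow variables for snapshot trajectory reconstruction"
author: "snapmatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Invariants and slow variables for snapshot trajectory reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snapmatch)
```

## The problem

Cytometry gives time-stamped snapshots: at each measurement time a fresh
aliquot of cells is stained and destroyed, so the same cell is never
observed twice. Whether cells can still be paired across two times depends
on the ratio ξ between how far a cell moves in abundance space during the
interval and the typical spacing between cells. Raw species abundances
usually give ξ ≫ 1 (many plausible partners); the strategy implemented here
is to construct a derived scalar per cell that moves as little as possible
while still differing between cells, so that matching in the derived
variable is (nearly) unambiguous.

## The two candidate invariants

**Total abundance.** I_T = Σ_{i∈S} x_i for a species subset S is exactly
conserved per cell whenever the kinetics only interconverts members of S —
a stoichiometric statement that survives nonlinearity and intrinsic noise.
For a linear system dx/dt = M x this corresponds to the columns of M
summing to zero over S.

**Whitened magnitude.** I_M = |J(t)^{-1/2} x(t)| with J(t) the population
covariance of the subset at the same time. For closed linear first-order
kinetics, x(t₂) = E x(t₁) with E = e^{MΔt}, means transform as μ₂ = E μ₁
and covariances as J₂ = E J₁ Eᵀ; hence J₂^{-1/2} E J₁^{1/2} is orthogonal
and the whitened vector's length is preserved cell by cell. Everything in
this argument is estimable from the snapshots themselves — no knowledge of
M is needed, which is the point: the rate matrix is *not* identifiable from
two snapshots (only n + n(n+1)/2 moment relations constrain its n²
entries), yet the invariant is.

Three implementation choices matter and are fixed deliberately:

- J uses the biased 1/N normalisation. The divergence bin-width rules
  below inherit J⁻¹, so the convention is applied uniformly rather than
  swapped for 1/(N−1).
- The matrix root is the **principal symmetric** PSD root via
  eigendecomposition. The orthogonality argument needs a symmetric choice;
  a Cholesky factor would break it.
- x is whitened **uncentred**. The invariance proof holds for raw vectors
  because the mean transforms by the same linear map; mean-centring first
  is available as `analysis_config(center_IM = TRUE)` but is not the
  default.

Degenerate covariances raise an error naming the near-constant species and
suggesting a ridge of 1e-9·tr(J)/k; any ridge actually used is recorded on
the returned object.

## Screening subsets with the Jensen–Shannon divergence

All 2ⁿ − n − 1 subsets of the measured panel (singletons excluded) are
organised into cardinality classes and scored: the JSD between the two time
points' distributions of I (for I_T and I_M) is compared against the JSDs
of each member species. Strictly beating the slowest member species makes I
a *slow variable* for that subset; a JSD of exactly zero makes it an
*invariant* — reported as a distinct state, since two zeros compare equal
under the strict inequality.

JSD is computed on shared-grid histogram masses. This equals the
discretised density integral because mass = density × width and the widths
cancel inside the logarithm; working with masses avoids zero-width
pathologies. Bins are anchored at the pooled minimum (the integral runs
from the observed minimum to the maximum, not from zero) and the last bin
is right-closed. Bin widths encode one-molecule measurement granularity:

- ΔI_T = k, the subset cardinality (a sum of k copy numbers is resolved to
  k molecules);
- ΔI_M propagates Δx = 1 through I_M = √(xᵀJ⁻¹x): per cell
  ΔI_M = (Σ_{ij} J⁻¹_{ij} x_j)/I_M, evaluated at both times with each
  time's own covariance, taking the minimum of the absolute values over all
  cells. Absolute values are needed because anticorrelated species make
  J⁻¹ row sums negative; a floor of (pooled range)/10⁵ guards the
  degenerate case where the minimum is numerically zero. Both choices are
  the package's own resolution of an under-specified rule and are applied
  identically everywhere.
- Individual species use width 1, consistent with the Δx = 1 convention,
  overridable in `analysis_config(species_bin_width = )`. This presumes
  abundances expressed as copy numbers of order 10²–10³ at ensemble sizes
  of order 10³; data on other scales should be calibrated or the width
  overridden accordingly.

One caveat is built in as a diagnostic: in a stationary stochastic regime
every distribution is frozen, so a vanishing JSD says nothing about
per-cell slowness. `steady_state_check()` (and the scan itself) flags the
case where *all* species distributions are unchanged and marks the scan
unreliable.

## Matching and its evaluation

The cost E = Σ_α (I⁽α⁾(t₁) − I^{β(α)}(t₂))² is minimised globally by rank
pairing: sort both value vectors and connect equal ranks — the classical
non-crossing rearrangement argument in the I–t plane. Sorting is stable and
ties are paired in original-index order; every tie-consistent pairing
attains the same E, so the choice is cost-neutral (though it can affect χ,
which is why it is documented). The ε(Δt)² term that makes the non-crossing
argument rigorous is a proof device and is not added numerically.

Baselines: exact Euclidean assignment (Jonker–Volgenant shortest
augmenting paths, refused above N = 5000 without an explicit override
because of its cubic cost), a seeded greedy nearest-neighbour variant for
large N, and seeded uniform random pairings.

Quality against ground truth is reported as:

- χ_α: Euclidean distance, over the evaluation subset's species, between
  the assigned sister cell and the correct partner. The squared variant is
  a config switch; zero-sets and orderings are identical.
- χ_Rel,α = Σ_i |x_i^(β) − x_i^(β′)| / |x_i^(β′)|: a per-species relative
  error for comparing subsets whose abundances live on different scales.
  Terms with a zero denominator are skipped and counted; cells with no
  valid term are excluded from means and reported.
- ΔA: the summed squared entrywise difference between cross-time
  correlation matrices (1/N, population means) under the evaluated and the
  correct pairing — exactly as defined, no square root.
- Each quantity also as a ratio to its mean over R seeded random pairings
  (R = 100 by default) with Monte-Carlo standard errors.

## The synthetic-data engine

The generator *is* the study design, so its defaults are fixed once:

**Linear networks.** `make_linear_network()` draws off-diagonal conversion
rates uniformly from 0.02–0.2 (reciprocal model-time units) on a random
sparsity pattern (density 0.3, plus a spanning conversion cycle so no
species is isolated), and sets the diagonal to minus the column sums for
the conservative case. With the default interval t = 0 → 7 the slowest
relaxation modes are still mid-course: the ensemble is genuinely out of
steady state, and the empirical covariances stay well-conditioned, which is
what keeps the I_M identity exact to ~10⁻¹² rather than drowned in
whitening round-off (an ill-conditioned J amplifies eigendecomposition
error by its condition number). Initial ensembles are multivariate normal
with means drawn from 100–1000 copies and 25% coefficient of variation,
clipped at zero (clip fractions are reported; a lognormal sampler is
available as an alternative).

**The Ras activation model.** A 14-species mass-action network with the
canonical T-cell Ras components: Ras cycling between RasGDP and RasGTP;
SOS with an allosteric Ras site whose RasGTP-bound form catalyses
RasGDP→RasGTP an order of magnitude faster than the RasGDP-bound form
(positive feedback); a RasGRP1 arm recruited by DAG through the complexes
RasGRP1-DAG and RasGRP1-DAG-RasGDP; deactivation by RasGAP with strongly
saturating kinetics (Km ≈ 11 copies) — the zero-order ultrasensitivity
that, combined with the SOS feedback, produces deterministic bistability in
RasGTP; and a DAG-kinase arm that sequesters DAG. Binding/unbinding rates
are an order of magnitude slower than catalysis, so after stimulus onset
(all complexes empty at t = 0) enzyme loading unfolds over ~100 s and the
bistable commitment of individual cells — driven by their own SOS, RasGAP
and Ras totals, which vary with 22% CV — over hundreds to thousands of
seconds. The 0→100 s interval is therefore a smooth, cell-specific
activation phase, while by 100–400 s the population visibly splits toward
the two branches. Copy numbers are of order 10–600 per species. The
`bistable` preset self-validates at construction by relaxing the mean cell
from a basal start and from a high-RasGTP start with the SOS allosteric
site preloaded (the high state lives on the loaded-enzyme manifold and is
unreachable from an all-free configuration); the `monostable` preset
(feedback reduced ~3×) must fail the same test. The RasGRP1 pool
{RasGRP1, RasGRP1-DAG, RasGRP1-DAG-RasGDP}, total Ras, total SOS, total
RasGAP, total DGK and total DAG are declared conservation groups, checked
stoichiometrically at construction and (in tests) along every simulated
trajectory.

**Propagation.** Linear ensembles use the matrix exponential
(`Matrix::expm`) — the exact solution. General networks integrate
mass-action ODEs per cell with `deSolve::lsoda` (rtol = atol = 1e-8;
integrating cells separately keeps the solver's numerical Jacobian at
n × n, which is dramatically cheaper than coupling the ensemble; tiny
negative excursions are clipped and counted). Stochastic kinetics uses an
exact Gillespie direct-method engine written in C++ with last-event-hold
recording and R's RNG stream, so `set.seed` governs reproducibility; no
tau-leaping is used — exactness is preferred at these problem sizes.

**Tracked vs batch mode.** Tracked mode records one cohort at every time
(ground truth = identity). Batch mode draws an independent, disjointly
seeded cohort per time point — as in real cytometry — and obtains each
interval's ground truth by forward-simulating the earlier batch to the
later time; for stochastic kinetics the correct partner is the same
realisation continued, i.e. the cell's own later state. The
measured-species projection (e.g. the six recorded species RasGTP, RasGDP,
SOS, RasGRP1, DAG, RasGAP) is applied only at recording, so ground truth
retains all species.

**What the generator does not emulate.** Measurement noise,
intensity-to-copy-number calibration error, spectral spillover,
debris/doublet gating, and cell death or division are all absent, and
initial variability is independent across species (no correlated totals).
Passing tests on these data therefore demonstrate the method's behaviour
under its own kinetic assumptions — extrinsic variability propagated
through known mass-action dynamics — not robustness to instrument effects.

## Experiment pipelines and problem sizes

`run_linear_experiment()` reproduces the ideal-kinetics study: a 14-species
conservative network, 3000 tracked cells, one interval, all 16 369 subsets
scored for both invariants, per-class minimum-JSD subsets used for
matching, χ and ΔA ratios against 100 random pairings. On this design the
full-panel I_M matching is exact, per-class χ ratios fall around 0.5–0.85,
and ΔA ratios sit well below 1 for all but the smallest classes (the
cross-correlation matrix is noisy for k = 2–3, where a small absolute ΔA
divides a small random baseline).

`run_ras_experiment()` reproduces the synthetic-cytometry study: 2000
cells per batch, stochastic kinetics, six recorded species, t = 0 vs
100 s, I_T scored over all 57 subsets, per-class minimum-JSD(I_T) subsets
matched and evaluated by χ_Rel ratios. `run_reconstruction()` chains
pairwise matchings over a longer series (successive intervals only, no
global multi-time optimisation) and, when the series was anonymised by
`strip_identities()`, scores each interval against the hidden truth.

These sizes — 3000 cells × 16 369 subsets, 2000-cell SSA batches — are the
package's reference experiment scale: large enough for stable moments and
histograms at the copy-number bin widths, small enough to run routinely on
a desktop. The exhaustive scan is capped at n = 20 species; beyond that an
explicit subset list must be supplied (no sampling heuristic is shipped —
the enumeration cost is the documented extension point).

## Numerical corner cases

- Histogram bin counts are derived with a relative tolerance (1e-9) so a
  value sitting exactly on the last edge does not split an invariant's
  histogram between two runs of the integrator.
- `inverse_sqrt_psd` rejects eigenvalues below −1e-10·‖J‖ as non-PSD and
  symmetrises its output explicitly.
- Ties in invariant values are not an error (cells in the same I_T plane
  are genuinely unresolvable by I_T); they are handled by the stable-sort
  tie rule in the matcher.
- `match_by_invariant` refuses unequal cell counts and points to
  `downsample_to_match()` (seeded subsampling without replacement).
- Subsets whose covariance is singular get `jsd_IM = NA` in the scan while
  I_T is still scored; `rank_subsets` ignores NA entries.

## Known limitations

The slow-variable screen compares distributions, not per-cell values: a
variable whose distribution is static while cells shuffle underneath it
(the stationary regime) is a false positive, which is why the stationarity
diagnostic is attached to every scan. Matching quality degrades as the
interval approaches an abrupt kinetic transition (the bistable jump in the
Ras model): rank matching cannot know *which* cells have committed, only
how the invariant orders them, and the interval-growth error trend in the
test suite quantifies exactly this. Finally, χ_Rel is dominated by species
with near-zero correct-partner abundances; its zero-denominator masking
reports, but cannot remove, that sensitivity.
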