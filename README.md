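# snapmatch

Reconstruction of single-cell trajectories from time-stamped snapshot data.

Flow and mass cytometry measure tens of signalling-protein abundances in
thousands of single cells, but destructively: every cell is assayed once, so
the populations measured at two time points contain *different, untracked*
cells. `snapmatch` implements a framework for re-connecting such populations
across time by constructing, from the measured abundances themselves, new
per-cell variables that are **invariants** (exactly constant along each
cell's kinetic trajectory) or **slow variables** (changing much less than
any measured species), and then pairing cells across time by matching the
values of these variables. The package is aimed at systems-biology analysts
working with cytometry-style snapshot data, and at modellers who want to
study when and why such reconstructions work.

## The variables and the method

For a cell α with species abundances x⁽α⁾ the two candidate invariants are

- **Total abundance** — for a species subset *S*,
  I_T⁽α⁾ = Σ_{i∈S} x_i⁽α⁾.
  Exactly conserved whenever the reactions only interconvert members of *S*
  (e.g. phosphorylation cycles, enzyme–substrate binding within the pool).

- **Whitened magnitude** — with J(t) the population covariance of the subset
  at time t (1/N convention) and μ its mean,
  I_M⁽α⁾ = | J(t)^{-1/2} x⁽α⁾(t) | = √( x⁽α⁾ᵀ J⁻¹ x⁽α⁾ ).
  For a closed system of first-order reactions, x(t₂) = e^{MΔt} x(t₁) and
  J(t₂) = e^{MΔt} J(t₁) e^{MᵀΔt}, so the whitened vectors at the two times
  differ only by an orthogonal map and I_M is exactly conserved per cell —
  computable from snapshot data alone, without knowing M.

For general (open, nonlinear, stochastic) kinetics neither quantity is
exactly invariant, but for particular species subsets it can still evolve
far more slowly than any member species. Candidate subsets are screened with
the **Jensen–Shannon divergence** between the two time points' distributions:
for each of the 2ⁿ − n − 1 subsets (singletons excluded), JSD of the
invariant's distribution is compared with the JSDs of the member species,
and the invariant is called *slow* when it beats the slowest species
(JSD^(I) < min_x JSD^(x)), or *invariant* when its JSD is exactly zero.
Histogram bin widths follow copy-number granularity: the cardinality k for
I_T, a one-molecule propagation rule for I_M.

Cells are then paired by minimising the cost
E = Σ_α (I⁽α⁾(t₁) − I^(β(α))(t₂))², whose global optimum for this
one-dimensional cost is attained by **rank matching** (sort both value
vectors, connect equal ranks, O(N log N)). Euclidean-assignment
(Jonker–Volgenant) and random baselines are included. Against ground truth
the package reports the per-cell error χ (distance between the assigned
"sister" cell and the true partner), its scale-free variant χ_Rel, and the
error ΔA between cross-time correlation matrices, all as ratios to the
random-pairing baseline.

A built-in mass-action simulator exercises the whole workflow on synthetic
data with known ground truth: a seeded generator of conservative linear
(first-order) networks propagated by the matrix exponential, and a
14-species bistable Ras-activation model (SOS positive feedback through its
RasGTP-bound allosteric site, RasGRP1/DAG activation arm, saturating RasGAP
deactivation) simulated deterministically (`deSolve`) or with the exact
Gillespie algorithm (Rcpp), in tracked or per-time-point-batch mode.

## Worked example

Generate a conservative linear 6-species system (1000 tracked cells,
multivariate-normal initial ensemble, one time interval), scan all 57
species subsets, and match cells on the whitened magnitude:

```r
library(snapmatch)
net <- make_linear_network(6, conservative = TRUE, seed = 1)
sim <- generate_snapshot_series(net, n_cells = 1000, times = c(0, 5), seed = 2)
s1 <- sim$series$snapshots[[1]]; s2 <- sim$series$snapshots[[2]]

scan <- scan_subsets(s1, s2)
summary(scan, "IM")
#> Per-class minima of JSD(I_M):
#>   k n_subsets       best_subset min_jsd jsd_slowest_species jsd_fastest_species  slow
#> 1 2        15             x3+x5  0.4820              0.6201              0.6463  TRUE
#> 2 3        20          x3+x4+x5  0.2556              0.3913              0.6463  TRUE
#> 3 4        15       x1+x3+x5+x6  0.1949              0.2028              0.6463  TRUE
#> 4 5         6    x1+x3+x4+x5+x6  0.3409              0.2028              0.6463 FALSE
#> 5 6         1 x1+x2+x3+x4+x5+x6  0.0000              0.2028              0.6931  TRUE
```

With all six species included I_M is an exact invariant (JSD = 0), and
matching on it recovers the true pairing exactly:

```r
m <- match_cells(s1, s2, method = "IM")
ev <- evaluate_matching(m, s1, sim$ground_truth[[1]]$partner_abundances, s2,
                        n_random = 100, seed = 3)
ev
#> <match_evaluation> N = 1000 cells, 6 species, method = invariant_sort
#>   mean chi     = 0  (random 126.94, ratio 0)
#>   mean chi_rel = 0  (random 0.94774, ratio 0)
#>   delta_A      = 0  (random 9.2717e+07, ratio 0)
```

On a partial subset I_M is only a slow variable, but matching on the
class-3 winner still roughly halves the error relative to random pairing:

```r
rk <- rank_subsets(scan, "IM")
best3 <- attr(rk, "subsets")[[which(rk$k == 3)]]
m3 <- match_cells(s1, s2, method = "IM", subset = best3)
evaluate_matching(m3, s1, sim$ground_truth[[1]]$partner_abundances, s2,
                  subset = best3, n_random = 100, seed = 3)
#> <match_evaluation> N = 1000 cells, 3 species, method = invariant_sort
#>   mean chi     = 47.382  (random 88.327, ratio 0.536)
#>   mean chi_rel = 0.28298  (random 0.51631, ratio 0.548)
#>   delta_A      = 8.8496e+06  (random 5.5201e+07, ratio 0.16)
```

The mean χ of 47.4 is the average distance (in copy numbers, over the three
subset species) between each cell's assigned sister and its true partner;
the ratios below 1 quantify the improvement over random pairing.

Data import/export uses a long CSV (`cell_id,time,<species...>`) or
per-time-point CSVs; `strip_identities()` anonymises tracked data while
hiding the ground truth in metadata for later scoring, and
`run_linear_experiment()` / `run_ras_experiment()` /
`run_reconstruction()` wrap the full pipelines. A command-line front end
with `simulate`, `score-subsets`, `match`, `evaluate` and `report`
subcommands is installed at `inst/cli/snapmatch.R`.

## Limitations

FCS files are not read directly (convert calibrated abundances to CSV
first); no spectral compensation or intensity calibration is performed; the
exhaustive subset scan is capped at 20 species. If every species
distribution is stationary across the interval, low invariant JSDs carry no
slow-variable information — the scan detects and warns about this regime.
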