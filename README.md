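# abcland

Likelihood-free calibration of a stochastic stem cell differentiation
model against single-cell snapshot data, with posterior sloppiness
analysis and quasi-potential (Waddington) landscape reconstruction.

## The problem

Single-cell experiments deliver *snapshots*: cross-sections of a cell
population at a few time points, with no linkage between cells across
time. Fitting a mechanistic model of differentiation to such data has no
tractable likelihood — each cell is an independent realization of a
stochastic gene network observed once. `abcland` implements the full
approximate Bayesian computation (ABC) route for this problem:

1. **Model.** A four-factor embryonic stem cell network — Nanog (N),
   Oct4-Sox2 (O), Fgf4 (F), Gata6 (G) — with Hill-type mutual repression
   between Nanog and Gata6, LIF support of Nanog, and linear degradation
   at rate γ:

   ```
   dN/dt = k0·O·(c0 + c1·N² + k0·O + c2·LIF) /
           (1 + k0·O·(c1·N² + k0·O + c2·LIF + c3·F²)) + c4·O·G² − γ·N
   dO/dt = α + (e0 + e1·O) / (1 + e1·O + e2·G²) − γ·O
   dF/dt = (a0 + a1·O) / (1 + a1·O) − γ·F
   dG/dt = (b0 + b1·G² + b3·O) / (1 + b1·G² + b2·N² + b3·O) − γ·G
   ```

   At the reference constants and LIF = 50 the system is bistable:
   pluripotent (high N / low G) and differentiated (low N / high G)
   states coexist.

2. **Stochastic simulation.** Exact Gillespie sampling of the
   corresponding jump process (compiled core), plus a chemical Langevin
   (Euler–Maruyama) approximation with per-reaction noise √aᵢ(x) dWᵢ.

3. **Snapshot data.** `generate_reference()` builds the species × time ×
   cells tensor (default 4 × 10 × 300) the inference targets.

4. **Distances between snapshot distributions**, per time point and
   summed: unbiased Gaussian-kernel MMD² (median-heuristic bandwidth),
   debiased entropic optimal transport (Sinkhorn divergence, annealed
   stabilized solver), Bhattacharyya distance via Silverman-rule KDEs
   (stable mixture-form estimator), and a Euclidean summary-statistic
   baseline.

5. **ABC–SMC** with the 30%-quantile tolerance schedule, adaptive
   multivariate Gaussian perturbation kernel and importance weights;
   tolerance targets calibrated from the distance distribution of
   true-parameter replicates (`separation_experiment()`,
   `suggest_epsilon()`).

6. **Posterior analysis**: PCA variance shares per parameter
   (`sensitivity_report()`), sloppy/stiff classification at a 1%
   variance-share threshold, pairwise Spearman structure.

7. **Landscapes**: `quasipotential()` reconstructs Ũ = −log p̂ over a
   gene pair (default Nanog–Gata6) and `basin_assign()` labels its
   wells by watershed flooding.

## Worked example

```r
library(abcland)

# reference snapshot data at the true parameters (LIF = 50)
ref <- generate_reference(n_cells = 100, seed = 100)
ref
#> <snapshot dataset: 4 species x 10 time points x 100 cells>

# how far apart are independent replicates at the truth?
sep <- separation_experiment(metric = "mmd", n_rep = 20, n_cells = 100,
                             seed = 1)
sep
#> <mmd separation: true-vs-true median 0.006197, prior-vs-true median 7.483, overlap 0.050>

# ABC-SMC with the MMD distance at desk scale
sim <- stem_simulator(n_cells = 100, time_grid = ref$time_grid)
res <- abc_smc(ref, sim, prior_spec(), snapshot_distance_fun("mmd"),
               epsilon_target = 0.06, N = 100, max_sims = 3e4,
               max_generations = 40, seed = 1)
res
#> <ABC-SMC: 10 generations, final tolerance 0.06, 12690 simulations [ok]>
#> tolerance schedule: 6.77, 4.37, 2.72, 1.44, 0.686, 0.41, 0.261, 0.18, 0.0983, 0.06

# which parameters does the posterior leave loosest?
pop <- final_population(res)
rep <- sensitivity_report(pop)
head(rep$table[order(-rep$scores), ], 4)
#>  parameter     score  percent  label
#>         e1 0.2364846 23.64846 sloppy
#>         c2 0.2269703 22.69703 sloppy
#>         e2 0.1492872 14.92872 sloppy
#>         b2 0.1268607 12.68607 sloppy

# Waddington landscape of a 300-cell reference ensemble
L <- quasipotential(generate_reference(n_cells = 300, seed = 1))
basin_assign(L)$minima
#>    i  j          x          y        U
#> 1 17 54  0.9555393 100.002112 8.599898
#> 2 40 21 92.0203306   2.219172 8.977408
```

The separation result says the MMD distance between replicate datasets
at the true parameters (~0.006) is three orders of magnitude below the
distance to prior-predictive datasets (~7.5), so an acceptance tolerance
placed near the true-replicate scale filters parameters sharply. The
ABC–SMC schedule then contracts from the prior-predictive scale (6.8)
down to 0.06 in ten generations. The sensitivity table lists the
weakly-constrained ("sloppy") posterior directions, and the landscape
has exactly two wells: the differentiated one near (1, 100) (the deeper,
as ~half the cells differentiate) and the pluripotent one near (92, 2).

A thin command-line wrapper over the same functions is installed at
`inst/cli/abcland.R` with subcommands `generate-reference`,
`calibrate-eps`, `run-abc`, `analyze-posterior`, `landscape`, `ppc`.

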