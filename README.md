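# splicedyn

Regulatory-network inference for alternative splicing along tumour
progression, from cross-sectional data.

During the epithelial-mesenchymal transition (EMT), RNA-binding proteins
(RBPs) rewire alternative-splicing (AS) patterns, but tumour cohorts only
provide snapshots: each specimen sits at an unknown point of the
transition. `splicedyn` is for computational biologists who have two
feature-by-specimen expression matrices (AS-event expression and RBP gene
expression) plus a binary epithelial/mesenchymal label per specimen, and
who want directed, signed regulatory networks among those features.

The method:

1. **Pseudotime.** Specimens are ordered by the leading diffusion
   component of a k-nearest-neighbour graph built from the standardised
   RBP profile, oriented so epithelial specimens sit at the head, and
   placed evenly on [0, 1].
2. **Trend selection.** Each feature, smoothed along pseudotime *s*, gets
   the score *R = |L/V|* (OLS slope over detrended standard deviation);
   the top 50 AS events and top 10 RBPs are kept by default.
3. **Dynamical system.** Expression follows mass-action kinetics
   (`dX_i/ds = sum_j a_ij X_i X_j + sum_l b_il X_i U_l - d_i X_i` for AS
   events; RBPs regulate each other but receive no AS feedback). Dividing
   each equation by its target linearises it, and the coefficients are
   estimated per equation by a Bayesian Lasso Gibbs sampler (Laplace
   prior as a scale mixture of normals). A directed edge is called
   wherever the 95% credible interval of a coefficient excludes zero;
   separate systems are fitted for the epithelial and mesenchymal
   segments of the trajectory.
4. **Ranking.** Hub nodes are ranked by maximal clique centrality and by
   out-degree; a two-sided Wilcoxon rank-sum filter supports targeted,
   single-gene analyses.

A full synthetic benchmark (sparse ground-truth systems, Runge-Kutta
simulation, shuffled specimens, multiplicative exponential noise) measures
ordering accuracy (Spearman rho, RMSE) and network recovery (ROC AUC,
accuracy, PPV, Matthews correlation) and drives the robustness and
prior-comparison studies.

## Worked example

Simulate a ground-truth system at the benchmark scale, shuffle it into a
cross-sectional cohort, and run the inference chain:

```r
library(splicedyn)

sys  <- sample_system(5, 3, seed = 42)          # sparse ground truth
traj <- simulate_trajectory(sys, sample_initial_conditions(5, 43),
                            sample_initial_conditions(3, 44),
                            seq(0, 1, length.out = 100))
cs   <- make_cross_sectional(traj, boundary = 0.5, seed = 45)

ord <- infer_pseudotime(cs$rbp_matrix, cs$annotation)
pseudotime_metrics(ord, cs$truth)
#>     rho rho_oriented     rmse
#> 1     1            1 6.05e-17

om  <- order_matrices(cs$as_matrix, cs$rbp_matrix, ord)
sm  <- smooth_trajectory(om$as_expr, om$rbp_expr, om$scores)
fit <- fit_system(sm, seed = 46)
fit$network
#> <regulatory_network: all state, 8 nodes, 4 edges>
#>   source target sign    mean  ci_low ci_high
#> 1 AS4    AS3    -     -0.493 -0.712   -0.221
#> 2 RBP1   RBP3   +      0.837  0.419    1.24
#> 3 RBP2   RBP3   +      0.637  0.0238   1.27
#> 4 RBP3   AS2    -     -0.799 -1.09    -0.467

edge_recovery_metrics(sys, fit$fits, fit$network)
#>     auc accuracy   ppv matthews
#> 1 0.928    0.902     1    0.668
```

The ordering is exact (rho = 1, RMSE ~ 0): the 100 shuffled specimens were
put back in their true progression order. The four called edges all carry
correctly signed coefficients (PPV = 1), and ranking every candidate
coefficient by `|posterior mean| / posterior sd` separates true from
absent interactions with AUC 0.93 on this seed.

Result objects are tibble-friendly: `tidy()` on fits and networks,
`glance()` for one-row summaries, `autoplot()` for trajectories,
orderings, networks, and robustness sweeps. Real data enter through
`read_expression()` / `read_annotation()` (tab-separated; `preprocess_matrix()`
applies the missing-row filter, kNN imputation and variance filter), and
`run_emt_analysis()` / `run_targeted_analysis()` run the whole workflow.
A thin command-line wrapper with `benchmark`, `run` and `targeted`
subcommands is installed at `inst/scripts/splicedyn`.

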