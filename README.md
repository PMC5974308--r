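# pathdyn

Predicting metabolic pathway dynamics from time-series multiomics data by
machine learning, for metabolic engineers and systems biologists who have
coupled proteomics + metabolomics fermentation time series and want
trajectory predictions — and design rankings — without hand-crafting a
kinetic model.

## What it does

Given time series of metabolite concentrations `m(t)` (n species) and
pathway enzyme concentrations `p(t)` (ℓ species) for a set of engineered
strains, `pathdyn` learns the metabolite vector field

    dm/dt = f(m, p)

as a supervised regression problem: each observation time contributes one
state–derivative training pair, and one regressor per metabolite is chosen
by tenfold cross-validated RMSE from a candidate registry (linear, ridge,
k-nearest-neighbour, random forest). Sparse series (~7 points over 72 h)
are Savitzky–Golay smoothed and spline-augmented to a dense grid before
differentiation. Trajectories for an unseen strain are predicted by
integrating the learned field with adaptive Runge–Kutta 45, using that
strain's protein series as input, from its first observed metabolite state.

The package also ships, as first-class tested components:

- a ground-truth **Michaelis–Menten kinetic model** of the
  limonene-producing mevalonate pathway (10 states, 9 enzymes) and a
  **virtual-strain generator** (leaky-Hill expression profiles
  `p(t) = k_f·t/(k_m+t) + k_l` with log-uniformly sampled coefficients),
- **evaluation**: continuous-time trajectory RMSE
  `sqrt((1/n) Σ_j ∫ (m̄_j − m_j)² dt)`, normalised percent error, and the
  **ranking** / **error-scaling** experiments that quantify how prediction
  quality grows with the number of training strains,
- a **kinetic-fit baseline** (differential evolution over
  `[1e-12, 1e9]`-bounded constants, evolved in log space),
- **PLS insight**: directions in final-time proteomics space that align
  with production, and simulated strains proposed along them,
- CSV/YAML/JSON I/O and a command-line interface
  (`simulate`, `preprocess`, `train`, `predict`, `evaluate`, `experiment`,
  `fit-kinetic`, `insight`) via `pathdyn_cli()` / `exec/pathdyn`.

## Worked example

Simulate a pool of virtual strains, learn the dynamics from ten of them,
and predict a strain the model has never seen:

```r
library(pathdyn)

model <- limonene_pathway_model()
pool  <- generate_pool(model, 12, seed = 1)
tidy(pool)
#> # A tibble: 12 × 2
#>   strain      final_product
#>   <chr>               <dbl>
#> 1 strain_0001          4.32
#> 2 strain_0002          4.63
#> 3 strain_0003          2.04
#> 4 strain_0004          2.93
#> # ℹ 8 more rows

train <- build_training_set(pool$series[1:10], target_points = 50)
fit   <- fit_dynamics(train, compact_search_space(seed = 1))
tidy(fit)
#> # A tibble: 10 × 3
#>    metabolite      candidate   cv_rmse
#>    <chr>           <chr>         <dbl>
#>  1 acetyl_coa      rf(100)     0.0243
#>  2 acetoacetyl_coa rf(100)     0.0104
#>  3 hmg_coa         rf(100)     0.0137
#>  4 mevalonate      rf(100)     0.00531
#>  5 mevalonate_p    rf(100)     0.0167
#>  6 mevalonate_pp   rf(100)     0.00593
#>  7 ipp             rf(100)     0.00348
#>  8 dmapp           ridge(0.01) 0.0122
#>  9 gpp             rf(100)     0.00654
#> 10 limonene        rf(100)     0.0137

heldout <- pool$series[[12]]
pred    <- predict_trajectory(fit, heldout)
pred
#> <trajectory_prediction> strain strain_0012, 7 time points, 1760 RHS evaluations

trajectory_rmse(pred, heldout)$total
#> [1] 8.264
attr(percent_error(pred, heldout), "average")
#> [1] 551.7
tail(heldout$`met:limonene`, 1); tail(pred$data$`met:limonene`, 1)
#> [1] 1.45
#> [1] 2.87
```

The `cv_rmse` column lists each metabolite's winning regressor and its
cross-validated derivative error (concentration units per hour; folds are
grouped by strain, so this measures cross-strain generalisation). The
trajectory metrics are honest about what small training sets buy:
predictions track the final product at the right scale, while the percent
error — averaged over all ten metabolites — is dominated by low-
concentration intermediates whose trajectories are only qualitatively
right. Design decisions should rest on the ranking experiments
(`ranking_experiment()`), which score exactly that use case, and improve
markedly as strains are added. `autoplot()` methods exist for series,
predictions, experiments and PLS results.

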