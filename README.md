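# jawrates

Comparative-methods pipeline for testing whether biomechanical
specialization along the jaw **velocity–force trade-off** acts as an
asymmetrical constraint on craniofacial evolution.

## The problem

Vertebrate jaws are lever systems: the mechanical advantage of the lower
jaw, MA = in-lever / out-lever, measures where a jaw sits on the inherent
trade-off between transmitting velocity (low MA) and force (high MA).
For a clade of fishes measured for MA and a set of craniofacial traits,
two macroevolutionary questions follow:

1. **Does specialization constrain the phenotype?**  Are jaws near either
   extreme of the trade-off less morphologically diverse than unspecialized
   jaws, and is the constraint symmetric between the two extremes?
2. **Does specialization change the rate of evolution?**  Do lineages with
   velocity- or force-modified jaws evolve craniofacial shape faster or
   slower than unspecialized lineages?

The package is aimed at comparative biologists with a phylogeny (Newick), a
per-specimen table of linear measurements, and these questions.  Because no
real measurement set ships with the package, a synthetic-data generator with
the same generative structure makes every stage testable end to end.

## What it computes

Working on a rooted phylogeny with Brownian-motion (BM) tip covariance
*C* (`bm_covariance()`):

- **Mechanical advantage and size correction.**  Species means of raw
  measurements; MA = il/ol; allometry removed per trait by phylogenetic GLS
  residuals of ln *trait* on ln *standard length*:
  β̂ = (XᵀC⁻¹X)⁻¹XᵀC⁻¹y, r = y − Xβ̂ (`phylo_residuals()`,
  `residual_matrix()`).
- **Shape–MA association.**  Ordinary PCA of the residual matrix
  (`shape_pca()`), then PGLS of each PC on MA with t-tests on n − 2 df
  (`pgls()`, `pgls_by_axis()`).
- **Disparity asymmetry.**  Species are classified velocity / unspecialized
  / force by a gradient of MA percentile cut-offs
  {10, 15, 17.5, 22.5, 33} (`classify_specialization()`).  Disparity is the
  variance V = (1/n) Σᵢ ‖xᵢ − x̄‖² of a group in residual trait space; the
  velocity-vs-force contrast D = V_velocity − V_force is tested by permuting
  tail labels (`disparity_asymmetry()`, `disparity_profile()`).
- **State-dependent rates (MuSSCRat-type).**  A Bayesian state-dependent
  multivariate BM model: traits evolve with tip covariance
  σ² C_rate ⊗ R, where the rate along each branch segment is σ² times a
  state multiplier ζ_state (mean pinned at 1, switched by a
  state-dependence indicator δ with prior ½) times compound-Poisson
  background shift multipliers (normalized to tree-wide mean 1).  The
  three-state character history is resampled by stochastic mapping inside
  the MCMC, so discrete and continuous evolution are estimated jointly
  (`run_mcmc()`, `mvbm_loglik()`, `sample_history()`).  The posterior
  probability of state dependence (PP) is the posterior mean of δ; rate
  ratios (RR) are posterior means/medians of ζ ratios given δ = 1.
  `summarize_grid()` averages PP and RRs over cut-offs × shift-number
  priors ({30, 40, 50} by default; {20, 40, 60} as an alternative preset).

`run_pipeline()` chains all stages from a config object or YAML file and
writes a CSV report bundle;
`inst/scripts/jawrates-pipeline.R` is a thin command-line front end with
verbs `simulate | residuals | pgls | disparity | rates | all`.

## Worked example

```r
library(jawrates)

## synthetic percid-like dataset: 89 species, ~300 specimens, with a
## three-fold force:velocity rate contrast
sim    <- simulate_dataset(sim_config(zeta_true = c(1, 1.5, 3),
                                      label_percentile = 33, seed = 1))
means  <- species_means(sim$measurements)
ma     <- setNames(mechanical_advantage(means$il, means$ol), means$species)
round(range(ma), 3)
#> [1] 0.193 0.441

resid  <- residual_matrix(sim$tree, means)
labels <- classify_specialization(ma, percentile = 33)
table(labels)
#>      velocity unspecialized         force
#>            30            29            30

dt <- disparity_asymmetry(resid, labels, n_perm = 999, seed = 1)
round(c(velocity = dt$disparity_velocity, force = dt$disparity_force,
        p = dt$p_value), 3)
#> velocity    force        p
#>    0.076    0.063    0.495

post <- run_mcmc(sim$tree, resid, labels,
                 priors = rate_priors(shift_lambda = 40),
                 n_gen = 150000, seed = 2)
post
#> State-dependent mvBM posterior (5000 samples, 150000 generations)
#>   PP(state-dependent) = 1
#>   RR force:velocity   = 2.8 (median 2.66)
#>   RR velocity:unsp    = 1.46 (median 1.38)
#>   RR force:unsp       = 3.78 (median 3.68)
```

Reading the output: species MA spans about 2.3-fold; at the 33rd-percentile
cut-off the two 30-species tails have similar disparity (this generator run
has no disparity asymmetry built in, and the permutation test correctly
finds none, p ≈ 0.5); the rate model recovers the simulated three-fold
force:velocity rate contrast (posterior median 2.66, truth 3) and is
certain the rates are state-dependent (PP = 1).  A result is flagged
`unconverged` whenever any retained scalar trace has an effective sample
size below 200.

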