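---
title: "Modeling the jaw velocity-force trade-off as a macroevolutionary constraint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the jaw velocity-force trade-off as a macroevolutionary constraint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

The lower jaw of a fish is a lever: its mechanical advantage
(MA = in-lever / out-lever) fixes the trade-off between transmitting
velocity (low MA) and force (high MA).  `jawrates` implements a complete
comparative pipeline for asking whether specialization along this trade-off
constrains craniofacial diversity and alters the rate of phenotypic
evolution.  This vignette documents the models, their assumptions, the
tunable parameters, the synthetic-data generator, and the numerical and
design choices a user or maintainer should know about.

## 1. Size correction by phylogenetic regression

All craniofacial traits scale with body size, so shape is analyzed as
phylogenetic residuals.  For each trait, the model is

$$\ln y = \beta_0 + \beta_1 \ln SL + \varepsilon,
  \qquad \varepsilon \sim N(0, \sigma^2 C),$$

where $SL$ is standard length and $C$ is the Brownian-motion (BM)
covariance of the tree ($C_{ij}$ = shared root-path length of tips $i$ and
$j$).  `phylo_residuals()` computes the GLS estimate
$\hat\beta = (X^\top C^{-1}X)^{-1}X^\top C^{-1}y$ and returns
$r = y - X\hat\beta$.  Both an intercept and a slope are estimated per
trait: the allometric slope is the quantity of biological interest, and an
intercept-only correction would conflate isometry with allometry.  The
residuals satisfy $X^\top C^{-1} r = 0$ (checked to $10^{-8}$ in the
tests).  On a star phylogeny ($C \propto I$) the fit reduces exactly to
ordinary least squares, which the test suite verifies against `lm()` to
$10^{-10}$.

Specimens are averaged within species on the raw millimetre scale before
the log transform (arithmetic means).  Averaging after the transform
(geometric means) is equally defensible; it is available via
`species_means(..., scale = "log")` and the default is recorded in the
pipeline configuration so the choice is explicit and reversible.

The six response traits are premaxilla, maxilla, nasal, oral cavity, snout
length, and the out-lever (mandible length).  The out-lever is a shape
trait in its own right; the in-lever is used only to form MA, so the
response matrix does not contain MA's numerator.

## 2. Classifying specialization

There is no objective MA value at which a jaw "becomes" specialized, so
classification sweeps a gradient of percentile cut-offs: at percentile $p$,
species with MA at or below the $p$-th percentile are velocity-modified and
those at or above the $(100-p)$-th are force-modified.  The gradient is
{10, 15, 17.5, 22.5, 33} (`specialization_cutoffs()`).  Percentiles use
linear interpolation between order statistics (R's default type 7); ties at
a threshold are assigned to the specialized tail so that tails are never
empty at the strictest cut-off.  Percentiles must lie strictly inside
(0, 50), otherwise the tails would overlap.  Lowering the percentile can
only shrink each tail (monotone nesting), which is tested as a property.

## 3. Disparity and the asymmetry test

Disparity of a group is its variance in residual trait space,
$V = \tfrac1n \sum_i \lVert x_i - \bar x \rVert^2$, equal to the trace of
the group's maximum-likelihood covariance matrix.  The asymmetry statistic
is $D = V_{\text{velocity}} - V_{\text{force}}$.  The null distribution is
built by randomly reassigning the velocity/force labels among the pooled
tail species with group sizes fixed, and the two-sided p-value is
$(1 + \#\{|D^\ast| \ge |D|\})/(n_{\text{perm}}+1)$, which is never zero and
never exceeds one.  Permuting group membership (rather than residuals)
matches the hypothesis actually at stake - equal disparity given the
observed group sizes - and is the convention of the standard morphometric
disparity tools.  The default is 999 permutations with a mandatory seed.
The test conditions on group membership and does not model phylogenetic
autocorrelation within tails; a clustered tail therefore shows low
disparity because its species genuinely share most of their history, which
is the biological signal of interest here, not a nuisance.

## 4. The state-dependent rate model

The core model is a Bayesian state-dependent multivariate Brownian-motion
model with background rate variation (a MuSSCRat-type model).  Let $Y$ be
the $n \times p$ residual matrix.  Conditional on a three-state character
history (velocity / unspecialized / force) painted along the branches, the
tip covariance is

$$\operatorname{cov}(y_{ik}, y_{jl}) = \sigma^2 \, C^{(\text{rate})}_{ij} R_{kl},$$

where $R$ is a $p \times p$ trait correlation matrix and
$C^{(\text{rate})}$ accumulates, along each branch segment, length
$\times$ state multiplier $\times$ background multiplier:

- **State multipliers** $\zeta = (\zeta_v, \zeta_u, \zeta_f)$ are positive
  with mean pinned at 1 ($\zeta = 3 \times$ Dirichlet(1,1,1) a priori), so
  they are identified separately from the overall rate $\sigma^2$.
- **State-dependence indicator** $\delta \in \{0,1\}$ with prior ½ switches
  the multipliers on or off; the posterior mean of $\delta$ is the
  posterior probability (PP) that evolution is state-dependent, i.e. the
  posterior frequency with which the state-dependent model is favored over
  a single-rate model.  The alternative (Bayes factors from marginal
  likelihoods) was deliberately not implemented: the indicator makes PP a
  simple posterior frequency and needs no bridge/path sampling.
- **Background rate variation** guards against mistaking lineage-specific
  rate heterogeneity for state dependence.  It is a compound-Poisson
  process: events fall uniformly on the tree (expected count $\lambda$,
  default presets {30, 40, 50}; the alternative preset {20, 40, 60} is also
  shipped because both gradients are in circulation), each multiplying the
  rate of everything tipward of it by a lognormal(0, 0.587²) factor (a
  typical shift of about two-fold).  Background rates are normalized to a
  tree-length-weighted mean of 1.  Without this normalization $\sigma^2$
  and the overall background level are confounded and the sampler mixes
  very poorly; with it they are identified.  This is the standard
  relaxed-clock convention.
- **Discrete character.**  The history is a symmetric three-state
  continuous-time Markov chain with a single exchange rate $q$ (exponential
  prior, mean 1).  Symmetry is the minimal-parameter choice; nothing in the
  data here would identify asymmetric exchangeabilities.  Tip states are
  fixed inputs (the classifier's labels), as in the empirical analyses this
  mirrors.

### Likelihood

`mvbm_loglik()` evaluates the model by Felsenstein pruning in
$O(n p^2)$: the traits are decorrelated with the Cholesky factor of $R$
(adding the Jacobian $-\tfrac n2 \log\det R$), and each decorrelated trait
contributes independent-contrast terms plus the density of its GLS root
state at the maximum (the root state is profiled out per trait).  The
tests verify exact agreement (to $10^{-8}$) with a dense
$np$-dimensional multivariate-normal evaluation on random trees, and the
exact rate-time confounding identity (doubling $\sigma^2$ while halving all
branch lengths leaves the likelihood unchanged).

### Stochastic mapping

Histories are drawn conditional on tip states by the standard two-pass
scheme: postorder partial likelihoods, then preorder sampling of node
states, then within-branch paths by uniformization.  For the symmetric
three-state chain with $\Omega = 3q$, the uniformized jump matrix is
$B = J/3$, so intermediate states are iid uniform and no rejection loop is
ever needed - the path draw is exact in one pass.  Conditional
transition-count means are validated against matrix-exponential
expectations (enumeration over internal states plus numerical integration)
within three Monte-Carlo standard errors.

### MCMC

`run_mcmc()` runs Metropolis-within-Gibbs (C++ core).  One generation is a
sweep over: a whole-tree history redraw (independence proposal from the
CTMC conditional) plus three subtree-restricted history redraws (the
whole-tree proposal alone suffers collapsing acceptance once the continuous
data inform the history - subtree moves restore mixing of $q$ and the
transition counts); a conjugate Gibbs draw of
$q \mid \text{history} \sim \Gamma(k+1,\, 2T + r)$; two pairwise simplex
slides on $\zeta$ (flat Dirichlet prior, Hastings ratio 1; when
$\delta = 0$, $\zeta$ is instead Gibbs-drawn from its prior, which is what
lets $\delta$ jump between models); a log-scale slide on $\sigma^2$
(half-Cauchy prior, scale 1); a $\delta$ flip; three correlation-pair
slides on $R$ (flat LKJ prior, positive-definiteness enforced by Cholesky
failure); and background birth/death (acceptance
$\lambda/(k{+}1)$ and $k/\lambda$ times the likelihood ratio) plus one
resize move.  Burn-in is 10%; thinning retains at most 5,000 samples; a
single seed determines the entire run.  Any retained scalar trace with
effective sample size below 200 (initial-positive-sequence estimator)
flags the result `unconverged` - it is returned, never suppressed.

Paper-scale runs of 500k generations are supported; the test suite and the
acceptance script use 20k-150k generations, which the prior-recovery and
parameter-recovery checks show is sufficient at the simulated problem sizes
(50-200 species, 1-6 traits).

Rate ratios are reported two ways: `rr` is the posterior mean of the
$\zeta$ ratios conditional on $\delta = 1$, and `rr_median` the posterior
median.  When a tail carries almost no information its multiplier's
posterior is nearly flat down to zero and the mean of the reciprocal ratio
becomes enormous; the median is the robust summary and is what the
recovery checks assert on.

## 5. The synthetic-data generator

`simulate_dataset()` is the generative mirror of the fitted model, not a
fixture: birth-death tree (`ape::rphylo`, conditioned on the tip count)
rescaled to unit root depth; ln MA by BM; labels from the same classifier
the analysis uses (so generative and inferential state definitions
coincide); a history consistent with those labels drawn by the package's
own stochastic mapping; six ln-traits = allometric component
(slope × ln SL, with ln SL itself BM) + correlated BM deviations whose
rates are scaled by the state history and by compound-Poisson background
shifts (same normalization as the likelihood); and specimen-level lognormal
measurement noise, with in-levers constructed as MA × out-lever so each
species' MA is reproduced exactly by its specimen means.

Default conditions: 89 species, 2-5 specimens per species (~300
specimens), root MA 0.35 with BM rate 0.06 so species MA spans roughly
0.22-0.56 (about three-fold), trait BM rate 0.02 on the ln scale (tip
shape SD ≈ 15%), exchangeable trait correlation 0.3, ten background
shifts of SD 0.4, and 1% specimen-level measurement noise.  The noise
level matters more than it looks: measurement error is unmodeled in the
rate likelihood, so species-mean error acts as extra tip-proximal variance.
At 5% it dominates the terminal-branch variance of a slow state, attenuates
the GLS allometric slopes, and biases tip-proximal state rates upward; at
1% - a realistic repeatability for digital linear measurements - it is
negligible.  Users simulating noisier data should expect exactly this
confounding in real analyses too; an explicit measurement-error variance in
the likelihood is a known limitation (below).

Two structural knobs shape where tail species sit on the tree, because
group disparity is governed by the ages of the divergences a group spans:

- `ma_jump` shifts one recently arising clade (youngest crown among clades
  holding 22-38% of tips) up the MA axis - force-modified jaws confined to
  a single young subclade;
- `ma_tip_sd` adds an iid species-level component to ln MA, scattering tail
  membership across anciently diverged lineages;
- `ma_velocity_jumps` (off by default) pushes several small distant clades
  toward low MA; `velocity_disparity_inflation` (off by default) adds iid
  species-level spread to velocity-tail traits.  The inflation knob must be
  used with care: because iid tip spread is indistinguishable from a fast
  tip-proximal state, inflation strong enough to move group disparity also
  inflates the inferred velocity rate.

`sim_config_asymmetry()` combines these into the asymmetrical-constraint
scenario used by the end-to-end checks: specialized states slower than
unspecialized with velocity slowest ($\zeta = (0.25, 1.9, 0.85)$, a
force:velocity rate ratio of 3.4), force tail young and clustered, velocity
tail old and scattered.  The velocity tail then spans deep divergences and
accumulates the greater disparity even though its instantaneous rate is the
lowest - high diversity through time-to-evolve, not through a fast clock -
while the rate model still recovers force:velocity > 1.  This is the one
configuration we found that produces both halves of the asymmetry signature
simultaneously under the model's own assumptions; making the force state
absolutely fast, or inflating velocity-tail variance with iid noise,
each produces one half while destroying the other.

What the generator does **not** emulate: measurement error in the
likelihood (see above), selection or convergence toward morphological
optima (no Ornstein-Uhlenbeck component - phenotypic "attraction" of
specialized jaws to a shared compact morphology cannot arise), fossil or
extinct sampling, and any generative link between MA and trait means (the
shape-MA regression slope is zero under the generator, so PGLS findings on
synthetic data reflect chance alone).  Passing tests therefore demonstrate
the estimators' internal correctness and calibration, not that real percid
data satisfy these assumptions.

## 6. Numerical choices and degenerate inputs

- $C$ and $X^\top C^{-1}X$ are factored by Cholesky; on failure a
  $10^{-10} \cdot \overline{\operatorname{diag}}$ jitter is added once
  (zero-length branches from deterministic polytomy resolution are the
  usual cause).  Constant size ($x$) is a hard error ("size has no
  variance").
- Pruning guards merge variances below $10^{-12}$ (zero-length cherries).
- PCA components are sign-fixed (largest-magnitude loading positive);
  trailing zero-variance components of rank-deficient inputs are retained
  with variance 0.
- A perfect PGLS fit ($\hat\sigma^2 = 0$) reports $p = 0$ and an infinite
  t rather than dividing by zero.
- Percentile ties at a cut-off go to the specialized class; if the two
  cut-offs collide (massive ties) classification errors out rather than
  producing overlapping tails.
- Polytomies are resolved deterministically (left-to-right, zero-length
  branches); all downstream BM covariances are invariant to the resolution.
- Newick parsing requires branch lengths everywhere (no silent defaults)
  and reports the character offset of unbalanced parentheses.

## 7. Known limitations

- No measurement-error term in the rate likelihood (species means are taken
  as exact), and no intraspecific variance component.
- Tip states are fixed by the classifier; uncertainty in the MA cut-off is
  explored only through the cut-off gradient, not modeled jointly.
- The discrete chain is symmetric with one rate; ordered or asymmetric
  transition schemes are not available.
- No OU or early-burst alternatives for the continuous model, and no
  reversible jump over the number of discrete states.
- The disparity permutation test does not condition on phylogeny within
  tails.
- Posterior-mean rate ratios are heavy-tailed near the $\zeta \to 0$
  boundary; prefer `rr_median` when a tail is weakly informed.
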