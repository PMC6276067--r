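---
title: "Stochastic mortality model pools, confidence-set trimming, and forecast combination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic mortality model pools, confidence-set trimming, and forecast combination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mortmcs)
```

## The problem

Pension funds and life insurers need forecasts of age-specific mortality
rates $m_{x,t}$ (deaths over exposure at age $x$ in year $t$) at
retirement ages, together with honest prediction intervals.  Many
extrapolative models exist — none dominates across populations, ages and
loss functions.  Rather than picking one winner, `mortmcs` fits a pool
of seventeen standard models, scores their one-step-ahead forecasts out
of sample, *trims* the pool down to the subset whose predictive ability
is statistically indistinguishable from the best (a model confidence
set), and averages the survivors' point and interval forecasts with
equal weights.  An inverse-validation-error weighting over the whole
pool is included as the baseline combiner.

## The model pool

All models act on log central death rates and are fitted per population
on an age $\times$ year grid (the canonical configuration is 41 age
groups, 60 to 100+, with the open group treated as the integer point
100).

**Poisson age–period–cohort family (labels 1–8).** Death counts are
$D_{x,t}\sim\text{Poisson}(e_{x,t}e^{\eta_{x,t}})$ with a log-link
predictor built from a static age term, bilinear age–period terms, and
an optional cohort term $\gamma_{t-x}$; see `?gapc_spec` for each
member's predictor and constraint set (Lee–Carter–Poisson,
Renshaw–Haberman, age–period–cohort, Cairns–Blake–Dowd, M6, M7, M8,
Plat).  Estimation is by alternating damped Newton updates of one
parameter vector at a time; each update has a closed form because the
predictor is linear in every block.  The deviance is guarded by step
halving, so it is non-increasing across sweeps (a test asserts this).
Convergence is declared when the relative deviance change drops below
`tol = 1e-6`, with a cap of 500 sweeps; the Renshaw–Haberman member is
warm-started from an age–period–cohort pre-fit and may legitimately
report `converged = FALSE` at the cap — its instability is a known
property of the model, and the fit is still returned with its flag.

Identifiability is imposed by invariance transformations
(`apply_constraints()`): bilinear terms are rescaled so loadings sum to
one and indexes to zero; cohort effects have the polynomial of the
constraint degree (mean, line, or quadratic in cohort year) transferred
into the age and period terms, which leaves the fitted predictor
unchanged.  Cohorts observed fewer than three times sit in the grid
corners and cannot support an effect of their own: they are pinned to
$\gamma=0$ and their cells get zero likelihood weight, so the
invariance property holds exactly on the cells that inform the fit.
The M8 constant $x_c$ is profiled over a candidate grid (default: the
twenty integer ages above the data range, acting as the age at which
the modulated cohort effect vanishes) by minimum deviance.

**SVD Lee–Carter family (labels 9–12).** $\ln m_{x,t} = \alpha_x +
\beta_x\kappa_t + \varepsilon_{x,t}$ with $\alpha$ the per-age mean and
$(\beta,\kappa)$ the rank-1 singular value decomposition of the
centered log rates.  The four variants differ in how $\kappa_t$ is
re-estimated per year holding $(\alpha,\beta)$ fixed: matching total
deaths, matching the age distribution of deaths (Poisson deviance),
matching period life expectancy, or no adjustment.  Because estimated
loadings can change sign across ages, the death-based targets need not
be monotone in $\kappa$; the implementation scans the $\pm 50$ window
for the sign change nearest the current value and polishes it with
Brent's method.  When no sign change exists, the target is infeasible
for that year and an error is raised — in the expanding-window exercise
such (model, origin) pairs are recorded as failures and excluded, never
zero-filled.

The life-expectancy target anchors at the youngest age held (60 in the
canonical configuration) rather than at birth, since the package sees
only the retirement-age window; the period lifetable uses mid-interval
deaths ($a_x = 0.5$) and closes an open-ended final group with
$L = l/m$.  Fitting-period selection à la Booth–Maindonald–Smith is not
implemented; label 10 is the deaths-distribution adjustment over the
full window.

**Functional time-series family (labels 13–17).** Log mortality curves
are first smoothed over age by a penalized cubic smoothing spline with
knots at every age, each age weighted by its death count (the
approximate inverse variance of a log rate), and with an optional
monotone projection (pool-adjacent-violators) above age 65, reflecting
that old-age mortality rises with age.  Functional principal component
analysis then gives $\ln m_t(x) \approx \mu(x) + \sum_k
\beta_{t,k}\phi_k(x)$.  The multi-population variants are the
product–ratio model (independent models for the log geometric-mean and
log square-root-ratio curves of a pair, which keeps the sex ratio from
diverging), a stacked multivariate fit, and a multilevel decomposition
into population means, a common trend, and population-specific
deviations.

### Outlier flagging in the robust variant

The robust variant deserves its own paragraph because the obvious rule
fails in two independent ways, both reproducible with this package's
generator.  First, a principal component basis fitted to contaminated
data will dedicate a component to a single outlying year, so the
outlier's own in-sample approximation error stays small — it masks
itself (with $K=6$, an injected one-log-unit shift was *never* flagged
in 20 trials).  Second, the per-year integrated squared error of raw
residuals is a weighted sum of heteroscedastic terms whose distribution
is far heavier-tailed than $\chi^2_{k-K}$, so that critical value
flags clean years routinely.  `robust_refit()` therefore (i) computes
each year's error out of sample, against a basis fitted with that year
left out; (ii) weights each squared residual by the cell's death count,
which standardizes the Poisson noise scale across ages and years; and
(iii) calibrates the $\chi^2$ degrees of freedom robustly by matching
the MAD/median ratio of the statistic, using the median-based scale the
procedure already needs.  Flagged years get weight zero in the final
fit.  Scores of flagged years are still computed (projections are
defined for every year) and the score series is extrapolated as a
whole; only the mean, components and variances exclude them.

## Forecasting

Score-driven models (labels 9–17) extrapolate every score series by a
random walk with drift.  The $h$-step variance includes the
drift-estimation term, $u_{n+h|n} = \hat\sigma^2 h(1 + h/(n-1))$ with
$\hat\sigma^2$ the maximum-likelihood innovation variance, and Gaussian
intervals use
$\mathrm{var}[\ln m_{x,n+h}] \approx \sum_k b_{k,x}^2 u_{k,n+h|n} + v_x$,
where $v_x$ is the per-age mean squared residual.  The Poisson family
simulates joint period-index paths from a multivariate random walk with
drift (drift = mean difference, innovation covariance = sample
covariance of differences) and, where a cohort term is present, future
cohort values from an ARIMA model selected by AIC over $p,q \in
\{0,1,2\}$, $d \in \{0,1\}$ (differenced fits keep an intercept, i.e. a
drift); the point forecast is the predictor at the index means and the
bounds are empirical quantiles over the simulated predictor, at the
default `n_paths = 1000`.  Parameter uncertainty is not simulated: the
interval reflects index (forecast) uncertainty for the Poisson family
and index-plus-residual uncertainty for the score-driven family.  All
simulation is seeded; repeating a call reproduces the forecast object
bit for bit.

The default interval level is 80% ($\alpha = 0.2$), the customary
setting for the interval score $S_\alpha = (u-l) +
\frac{2}{\alpha}(l-y)1\{y<l\} + \frac{2}{\alpha}(y-u)1\{y>u\}$, whose
exceedance factor is then 10.

## Evaluation, trimming, combination

`expanding_window()` refits every model on data up to each origin year
and forecasts one step ahead; with the canonical plan (train to 1995,
validate to 2005, test to 2015) this yields ten validation and ten test
forecasts per model.  Losses are computed on the log-rate scale — the
scale every pool member actually models — as per-curve RMSFE or mean
interval score; a multiplicative change of rate units shifts forecasts
and actuals identically and leaves the losses unchanged (asserted by a
test).

The model confidence set works on the loss matrix: pairwise loss
differentials $\bar d_{\rho\xi}$ and their row means, studentized by
moving-block bootstrap variances, give the range statistic
$T_R = \max|t_{\rho\xi}|$ or the semi-quadratic
$T_{max} = \max t_{\rho\cdot}$; the null distribution comes from the
same bootstrap replicates with differentials recentered at their sample
means.  The worst model (standardized elimination rule matching the
statistic; the standardized form is used for $e_{max}$ as well, since
an unstandardized denominator would be inconsistent with the
$t_{\rho\cdot}$ definition) is removed and the test repeats on the
survivors, with the bootstrap redrawn under a deterministically
advanced seed, until the p-value reaches the test level $\alpha$ (0.10
for a 90% set).  MCS p-values are the running maximum of step p-values,
hence non-decreasing along the elimination order; retention at level
$\alpha$ is equivalent to an MCS p-value of at least $\alpha$, so
superior sets are nested across levels.

The bootstrap block length comes from the loss differentials: an AR
model per pairwise series, order chosen by AIC up to $\lfloor
N^{1/3}\rfloor + 1$, refitted by least squares.  A significant lag-$\ell$
coefficient means dependence that only survives resampling in blocks of
$\ell+1$ points, so the block length is one plus the largest
significant-coefficient count over pairs — independent differentials
give 1, autocorrelated ones at least 2.  Significance is judged at a
Bonferroni-corrected 5% across the candidate lags; with the plain 1.96
cutoff, spurious lags are "found" in roughly a quarter of white-noise
series, which would inflate block lengths for independent losses.
With fewer than five evaluation points no AR fit is meaningful and the
block length falls back to 1.

Combination is convex: the trimmed combiner puts weight
$1/|\text{superior set}|$ on each survivor and zero elsewhere; the
baseline puts weight proportional to inverse mean validation loss on
every model.  Interval bounds are averaged with the same weights —
averaging the member quantile curves rather than mixing predictive
distributions; the combined interval therefore lies in the convex hull
of the members' intervals.

## The synthetic-data generator

`ground_truth()` / `simulate_surface()` define the study conditions for
every test: 41 ages (60–100+), years 1975–2015, a Gompertz age profile
$\alpha_x = -9 + 0.09(x-60)$, loadings $\beta_x$ drawn uniformly on
$(0,1)$ and normalized to sum to one (drawn reproducibly from the
ground-truth seed; a constant profile would have no variance to
recover), a random-walk-with-drift period index (drift $-0.5$,
innovation SD $0.3$; with $\sum\beta = 1$ that is a realistic ~0.5
log-unit average mortality decline over the sample), exposures of
$10^5$ person-years per cell, Poisson death counts, an additive 0.3
log-rate offset for the male member of a pair, and correlated
populations mixing one shared index path with idiosyncratic ones.  A
deterministic mode replaces sampling with expected counts for
exact-recovery tests, and `inject_outlier_years()` bumps chosen years'
log rates for the robustness checks.

What the generator does *not* emulate: smooth age loadings (real
$\beta_x$ profiles are smooth in age, so age-smoothing helps real data
more than it helps these fixtures), cohort effects (off by default),
heterogeneous exposure by age, and jumps or wars.  Passing tests
therefore certify the estimation and testing machinery, not empirical
forecast rankings on any real population.  One consequence is worth
recording: at exposure $10^5$ the sparsest cells (age 60) carry only
about a dozen deaths a year, so the log-rate noise floor caps the
recovery correlation of equally-weighted estimators (SVD Lee–Carter,
FPCA) at roughly 0.98 for the period index and 0.95–0.97 for the
loadings; only the Poisson-weighted Lee–Carter reaches 0.995 on the
index.  The acceptance suite asserts the stricter 0.99 everywhere and
is expected to fail on exactly the FPCA-score and Poisson-beta
expectations — an intrinsic property of these study conditions, not an
estimator defect.

## Numerical and design choices

* Zero death counts keep rate 0 in storage; log-domain consumers
  replace a zero by half the smallest positive rate in the same year's
  column (`log_safe_rates()`), avoiding $-\infty$ while preserving
  within-column ordering.
* The open age group "100+" is the integer 100 on every model age
  scale, including $\bar x$ and $(x - \bar x)$ terms.
* FPCA component signs are fixed by making each component's
  largest-magnitude coordinate positive; SVD sign ambiguity is resolved
  by the $\sum\beta = 1$ normalization itself.
* Defaults: $K = 6$ components for single-population functional
  variants, $K_{common} = K_{specific} = 3$ for the multilevel model,
  robust flagging level 0.999, interval level 0.8, MCS level 0.10,
  $B = 5000$ bootstrap replicates (pipeline configs use smaller $B$
  where stated), 1000 index paths.
* Problem sizes in the shipped tests: surfaces of 41 ages by 21–42
  years, bootstrap sizes 150–2000, 200-replication size/power and
  coverage studies, and a six-model end-to-end pipeline on the
  1975/1995/2005/2015 plan — sizes at which every behavior asserted is
  already visible and the whole suite runs in a few minutes.

## Known limitations

Parameter uncertainty is excluded from Poisson-family intervals; no
Gaussian/binomial GAPC link variants; no multi-horizon joint evaluation
(each horizon is evaluated separately); no cross-validation of $K$; no
coherence constraints beyond what the product–ratio and multilevel
structures impose; the inverse-error baseline requires strictly
positive validation losses.  The Renshaw–Haberman member can hit its
iteration cap on short windows — it is reported, not hidden.
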