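---
title: "Methods: occupancy modeling, model selection, and the synthetic survey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupancy modeling, model selection, and the synthetic survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The inference problem

Repeat-visit point counts record whether a species was detected, not
whether it was present: a zero can mean an empty site or a missed bird.
The single-season occupancy model separates the two with a latent
occupancy state per site-unit and a detection sub-model per visit,

$$z_i \sim \mathrm{Bernoulli}(\psi_i), \qquad
  y_{ij}\mid z_i \sim \mathrm{Bernoulli}(z_i\, p_{ij}),$$

with $\mathrm{logit}(\psi_i) = x_i^\top\alpha$ and
$\mathrm{logit}(p_{ij}) = w_{ij}^\top\beta$. The *site-unit* here is a
point-count location in one survey year with $J = 2$ replicate visits;
occupancy is assumed closed within a winter season (the closure
assumption), and year enters as an occupancy covariate rather than as a
second season. Points within a wetland are treated as independent
site-units; no wetland-level random effect is fit, which matches the
model the package is designed around but understates dependence if birds
move among points of one wetland.

Marginalizing $z_i$ gives the integrated site likelihood used everywhere
outside the sampler (and in WAIC):

$$L_i = \psi_i \prod_j p_{ij}^{y_{ij}}(1-p_{ij})^{1-y_{ij}}
       + (1-\psi_i)\,\mathbf{1}\!\left[\textstyle\sum_j y_{ij}=0\right].$$

All likelihood computation is done in log space; the two-term sum uses a
stable pairwise log-sum-exp, because $\psi\prod_j(1-p_{ij})$ underflows
for extreme linear predictors. Missing visits are dropped from the
likelihood (and from the detection design matrix), never imputed; a
site-unit must retain at least one realized visit.

# Priors and sampling

Every coefficient, intercepts included, has an independent standard
logistic prior. This choice has a useful calibration property: a
logistic(0, 1) variate pushed through the inverse logit is exactly
Uniform(0, 1), so an intercept-only sub-model is *a priori* flat on the
probability scale. The test suite exploits this identity — prior-only
runs of the sampler must produce uniform probabilities (Kolmogorov-
Smirnov check at 10,000 retained draws).

The posterior is sampled by data-augmented Metropolis-within-Gibbs:

1. each latent $z_i$ is Gibbs-drawn from its full conditional
   ($z_i = 1$ whenever any visit detected the species, otherwise
   $\psi_i q_i / (\psi_i q_i + 1 - \psi_i)$ with
   $q_i=\prod_j(1-p_{ij})$);
2. each occupancy coefficient is updated by a Gaussian random-walk
   Metropolis step against the Bernoulli likelihood of the augmented
   states plus the prior;
3. each detection coefficient is updated the same way against the visit
   likelihood restricted to currently occupied site-units.

Proposal standard deviations start at 0.5 and adapt in batches of 50
iterations during burn-in toward a 0.3 acceptance rate (step size
$\min(0.1, 1/\sqrt{\text{batch}})$ on the log scale); adaptation is
frozen at the end of burn-in so the retained chains are Markov, and the
retained-phase acceptance rates are reported on the posterior object.
Coefficients start at 0 and latent states at 1 wherever a detection
occurred (elsewhere Bernoulli(0.5)), which cannot produce a non-finite
initial posterior for finite data; the sampler still verifies this and
aborts with a re-initialization message otherwise. Chains are seeded
`seed + chain - 1`, making every run bit-reproducible. Any correct
sampler targeting the same posterior would be equally valid — the
package asserts *distributional* equivalence, and one test cross-checks
the posterior mean and spread against an independent general-purpose
Gibbs engine (JAGS) on an intercept-only fixture.

Defaults mirror the analysis the package was built for: 4 chains of
10,000 iterations, thinning by 5, burn-in 2,500 (5,000 for the
slower-mixing song and swamp sparrow fits, which the pipeline applies
per species); all are configurable.

# Summaries, reduction, and model choice

Posterior summaries report the mean, median, and equal-tailed 50% and
95% intervals using type-7 (linearly interpolated) empirical quantiles —
stated explicitly because the covariate-reduction rule consumes these
intervals and tests pin them exactly. Convergence is monitored with the
classic split-chain Gelman-Rubin $\hat R$ (each chain halved, no rank
normalization, matching the era of tooling the workflow reproduces).
Note the classic estimator may dip slightly *below* 1 by $O(1/n)$
sampling noise when chains agree; it is reported as `NA` for parameters
with zero within-chain variance.

The global model (all nine occupancy and six detection covariates, 19
coefficient columns) is reduced by retaining a covariate iff at least
one of its coefficients has a 50% credible interval excluding 0,
separately for the two sub-models; categorical covariates are kept or
dropped as whole dummy blocks, because dropping individual levels would
silently change the reference coding. Intercepts are always kept.

One calibration fact shapes what reduction can and cannot do: for a
truly null covariate a well-calibrated 50% interval *covers* zero only
about half the time, so the rule discards nulls at roughly a 50-65% rate
(a bit more under the logistic prior's shrinkage), while covariates with
strong effects (|coefficient| around 1.5 on the standardized scale at a
few hundred site-units) survive nearly always. The property tests
encode exactly this: strong effects retained in at least 80% of
replicates, nulls dropped at a rate bounded well below certainty. A
reduced model is therefore parsimonious-leaning, not an oracle, which is
why the reduced and global fits are then compared by WAIC and only the
lower-WAIC model is reported.

WAIC is computed from the pointwise *site-unit* integrated
log-likelihood matrix (latent state marginalized out — per-visit terms
are not exchangeable under the latent state), with
$\mathrm{lppd}=\sum_i \log \frac1S\sum_s \exp \ell_{si}$ via
log-mean-exp and the variance-form penalty
$p_{\mathrm{WAIC}}=\sum_i \mathrm{Var}_s(\ell_{si})$ (sample variance,
$S-1$ denominator), the standard recommendation among the penalty
variants. Comparison tables break WAIC ties toward fewer coefficient
columns $K$ (intercepts included in $K$).

# Derived quantities

`occupancyAtProfile()` evaluates $\psi$ draw-by-draw at a covariate
profile. "Held at the mean" is implemented as the design-column means —
for categorical covariates that is the mean of the dummies, an "average
site", a definition chosen explicitly since a categorical covariate has
no unique mean level. `oddsRatioCurve()` reports, per draw,
$\mathrm{LOR}(s)=\alpha_{\mathrm{size}}\,(z(s)-z(\mathrm{ref}))$ against
a reference wetland size, so the curve is exactly linear per draw with a
zero-width band at the reference. The reference statistic defaults to
the sample *median* (10.8 ha in the motivating survey) but is
configurable to the mean or any value, since the two conventions differ
in skewed size distributions.

# The richness model

Apparent species richness — distinct species detected, uncorrected for
detection — is counted per wetland-year (the wetland, not the point, is
the replication unit; wetland-year rows are used because year is a model
term) and modeled as Poisson with log link on wetland type, standardized
size, and year. The fit delegates to `stats::glm`, i.e. iteratively
reweighted least squares run to a $10^{-10}$ relative deviance change,
with Wald normal-approximation p-values; a rank check rejects aliased
designs before fitting, and no overdispersion correction is applied (the
workflow reproduces a plain Poisson fit). Because size enters
standardized, its coefficient reads as log proportional change in
expected richness per SD of wetland size; the mean/SD are returned so
raw-scale effects can be recovered.

# The synthetic survey

The generator emulates the design envelopes of the motivating two-winter
survey, not its empirical joint distributions (only envelopes are
observable from the published summaries):

* 33 wetlands, 20 ACEP and 13 reference, sizes log-uniform on
  0.28-32.4 ha;
* 1-9 points per wetland via $1+\mathrm{Binomial}(8, 3/8)$ (mean 4),
  two years, two visits per point-year;
* continuous detection covariates uniform over their observed ranges
  (time 6.85-15.22 h, wind 0-4.5 m/s, temperature -12.2-17.8 °C, noise
  0-67 dB, day of season 1-102) and categorical covariates multinomial
  with the observed proportions (e.g. 1x1 m shrub 0.77/0.23, sky
  0.56/0.44);
* detection histories generated from the occupancy model itself, with
  the latent states emitted in a side table for white-box tests only;
* richness from the Poisson model above, default coefficients set to
  the reported magnitudes (type -0.05, size +0.2, year -0.08, intercept
  log 18 — a typical winter wetland species count).

Default species effects give each focal species a plausible profile
(e.g. a common, shrub-avoiding species whose detectability declines
through winter; sparse species tied negatively or positively to wetland
size), with effect sizes at the reported coefficient magnitudes. What
the generator does *not* emulate: spatial structure among points,
correlation between vegetation covariates (they are drawn
independently, which is also why the collinearity screen passes by
construction), observer effects, and temporal autocorrelation of
weather. Passing tests therefore demonstrate that the estimator
recovers the generative process under the design's sample sizes — they
do not certify the model against violations such as non-closure or
unmodeled heterogeneity in real data.

# Test and check sizes

Stochastic checks are sized for a single CPU while keeping false-failure
probabilities small by design, chosen once from binomial calculations
rather than tuned: parameter recovery uses ~500 site-units per dataset
with 8 replicate datasets and a ≥6/8-coverage rule per parameter
(~$10^{-3}$ false failure for a calibrated sampler — a single dataset's
95% interval misses its generative value ~5% of the time even when
everything is correct); interval-coverage calibration pools 50
intervals from 25 replicates at ~300 site-units against an 85% bound;
reduction power uses 12 replicates at ~400 site-units with |effect| =
1.5. The acceptance script fits two species' global (19-coefficient)
and reduced models at the survey's own scale (~260 site-units) with 4
chains of 4,000 iterations — enough for $\hat R < 1.05$ on every
coefficient there; the package defaults remain 10,000.

# Known limitations

Single-season only (no colonization/extinction dynamics); no abundance
mixture; no spatial or wetland-level random effects; richness is
apparent, not detection-corrected; the componentwise random-walk sampler
is simple and robust but mixes more slowly than gradient-based samplers
on strongly correlated posteriors, which is why per-species burn-in
defaults differ.
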