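# occubayes

Bayesian single-season occupancy models with imperfect detection, WAIC
model selection, and Poisson species-richness regression for replicated
winter point-count surveys of wetland birds.

The package is written for wildlife biologists and quantitative ecologists
analyzing detection/non-detection data from repeat-visit point counts —
the motivating setting is a two-winter survey of Passerellidae sparrows
(song sparrow, swamp sparrow, dark-eyed junco, white-throated sparrow) on
restored agricultural-easement (ACEP) wetlands versus reference wetlands,
where the questions are whether occupancy and apparent avian richness
differ by wetland type after controlling for vegetation, wetland size and
survey conditions.

## The model

Each site-unit *i* (a point-count location in one survey year, assumed
closed within the season) has a latent occupancy state and J = 2 replicate
visits:

```
z_i  ~ Bernoulli(psi_i),        logit(psi_i) = x_i' alpha     (occupancy)
y_ij ~ Bernoulli(z_i * p_ij),   logit(p_ij)  = w_ij' beta     (detection)
```

Occupancy covariates `x_i` are wetland type, size, year, and vegetation
structure; detection covariates `w_ij` are time of day, sky condition,
wind, temperature, ambient noise and day of season. All coefficients get
independent logistic(0, 1) priors (flat on the probability scale for an
intercept). The posterior is sampled with a data-augmented
Metropolis-within-Gibbs algorithm: the latent `z_i` are Gibbs-drawn from
their full conditionals and each coefficient is updated by an adaptive
componentwise Gaussian random walk (adaptation frozen after burn-in).

A *global* model with every covariate is reduced by dropping all
covariates whose coefficients' 50% credible intervals overlap 0
(categorical covariates move as whole dummy blocks); global and reduced
models are compared with WAIC, `-2(lppd - pWAIC)`, computed from the
pointwise site-unit marginal likelihoods with the variance-form penalty.
Apparent species richness per wetland-year is modeled as
`richness ~ Poisson(exp(b0 + b_type + b_size * sizeZ + b_year))`.

A synthetic-data generator reproduces the survey design (33 wetlands, 1-9
points each, 2 years x 2 visits, covariates drawn over the observed
ranges and category proportions) from known coefficients, so the whole
pipeline is testable without field data.

## Worked example

```r
library(occubayes)

study <- simulateStudy(simulationScenario(seed = 1))
det <- study$detections$deju
det
#> DetectionTable ('deju'): 262 site-units (131 points, 33 wetlands), 2 visits
#>   naive occupancy: 0.237; missing visits: 0

fit <- fitOccupancy(det, study$siteCovs, study$surveyCovs,
                    modelSpec("deju", occupancy = "size", detection = "time"),
                    mcmcConfig(nChains = 2, nIterations = 2000,
                               nBurnin = 500, seed = 1))
summarizePosterior(fit)
#>         parameter  mean median lower50 upper50 lower95 upper95 rhat
#> 1 psi_(Intercept) -1.43  -1.42  -1.603   -1.25   -1.92   -0.95    1
#> 2        psi_size -1.82  -1.81  -2.079   -1.55   -2.65   -1.03    1
#> 3   p_(Intercept)  0.28   0.29   0.098    0.46   -0.24    0.78    1
#> 4          p_time  0.63   0.62   0.481    0.78    0.21    1.09    1

waic(fit)
#> WAIC = 380.50  (lppd = -186.33, pWAIC = 3.92, 262 site-units)

occ <- occupancyAtProfile(fit)
sprintf("occupancy at mean covariates: %.2f (95%% CI %.2f-%.2f)",
        occ$mean, occ$lower, occ$upper)
#> "occupancy at mean covariates: 0.20 (95% CI 0.13-0.28)"
```

The junco data were generated with a true wetland-size effect of -1.6 on
the logit scale and a time-of-day detection effect of +0.8; the posterior
recovers both (size -1.82 [-2.65, -1.03]; time 0.63 [0.21, 1.09]) and all
R-hat values are ~1.00. `naiveOccupancy` (0.237) is the raw fraction of
site-units with a detection; the model-based estimate at mean covariates
(0.20 with detection probability near `invLogit(0.28) = 0.57` per visit)
separates true absence from missed detection. `reduceModel()` then drops
50%-interval-straddling covariates from a global fit, `compareModels()`
ranks the global and reduced fits by WAIC, `oddsRatioCurve()` traces the
size effect against the median-sized wetland, and `fitRichnessGLM()` fits
the richness regression. `runPipeline()` (or
`inst/scripts/occupancy-pipeline.R` from a shell) runs all of it from a
YAML config and writes CSV tables plus a reproducibility manifest.

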