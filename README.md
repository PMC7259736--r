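# occuselect

Hierarchical Bayesian site-occupancy modelling with cross-product model
selection, built for repeated point-count surveys of Clark's nutcracker
(*Nucifraga columbiana*) in whitebark pine (*Pinus albicaulis*) ecosystems.

Whitebark pine depends on Clark's nutcracker for seed dispersal, and managers
planning restoration need to know which habitat quantities — presence and
density of cones, local importance value of whitebark pine or Douglas-fir, or
the area of those habitats on the surrounding landscape — best predict where
nutcrackers occur during each stage of their annual cycle. Because a bird
present at a site is often missed on any single ten-minute count, raw
("naive") occurrence understates use, and the analysis must model detection
and occurrence jointly. This package provides that analysis as a reusable,
tested pipeline, together with a seeded synthetic-data generator that
emulates the survey design so every stage of the pipeline can be validated
against known truth.

## The model

Each survey unit is one site `i` in one stage `s` of one year `y`, with a
detection history of three sequential ten-minute counts,
`h ∈ {0,1}³`. The latent state `z ~ Bernoulli(ψ)` is whether the site is
used; counts are conditionally independent Bernoulli(`z·p`) draws:

```
logit(ψ_i)  = α_s + u_site + Σ_j a_j β_{j,s} x_ij      (occurrence)
logit(p_i)  = μ_p + ε_{y,s} + η_i                      (detection)
u_site ~ N(0, σ_site²),  ε_{y,s} ~ N(0, σ_p²),  η_i ~ N(0, σ_obs²)
```

The inclusion indicators `a_j` are governed either by per-covariate
Kuo–Mallick indicators with a Bernoulli(0.5) prior (phase-one screening by
posterior inclusion probability, retaining covariates with
`P(I_j = 1 | y) > 0.5`), or by a latent per-stage categorical model
indicator ranging over an enumerated candidate set (cross-product model
selection); the indicator's posterior frequencies are the posterior model
probabilities, and summarising a coefficient only over draws in which it is
included yields model-averaged ("conditional") estimates. Zero-inflated
covariates (cone density, importance values) enter as an
absence-indicator/magnitude pair that is included or excluded together.
Everything is fitted by a Metropolis-within-Gibbs sampler with explicit
data augmentation of `z`, diffuse `N(0, 10²)` priors on logit-scale
locations and `Uniform(0, 10)` priors on standard deviations.

Model fit is checked with a Bayesian MacKenzie–Bailey test: the
detection-history chi-square discrepancy is computed for the data and for a
posterior-predictive replicate at each draw, and fit is adequate when the
95% credible interval of `T_rep − T_obs` includes 0. Fitted models feed
occurrence-probability prediction curves with credible bands and
habitat-area threshold estimation (e.g. the smallest landscape area of
whitebark pine giving ≥ 75% predicted occurrence), and observed occurrence
can be compared against the earlier published cone-crop models (a linear
and a beta-regression formula) with Spearman and one-tailed Wilcoxon
signed-rank tests.

## Worked example

Simulate one fall-harvest season in which occurrence depends on cone
presence, cone density and the landscape area of whitebark pine, then let
the sampler pick the model:

```r
library(occuselect)

sc <- sim_scenario(
  n_sites = 200, years = 2013, stages = "fall_harvest",
  mu_p = qlogis(0.65), sigma_p = 0, sigma_obs = 0, sigma_site = 0,
  alpha = c(fall_harvest = 0.5),
  beta  = list(fall_harvest = c(cone_density_absent = -1.5,
                                cone_density = 1.0, wbp_area = 0.8)),
  seed = 11)
sim <- generate_detections(sc)
dat <- as_occu_data(sim$records,
                    design_subset(sim$X, c("cone_density_absent",
                                           "cone_density", "wbp_area",
                                           "df_area")))
fit <- occu_mcmc(dat, model_sets = final_candidate_sets(stages = "fall_harvest"),
                 settings = mcmc_settings(seed = 5),
                 site_re = FALSE, det_re = FALSE)
sel <- summarize_selection(fit)
sel
#> fall_harvest model probabilities:
#> M1 M2 M3 M5
#>  0  0  0  1
sel$fall_harvest$conditional
#>                  term      mean      lower      upper inclusion_prob
#> 1 cone_density_absent -1.590198 -2.5176975 -0.7120292              1
#> 2        cone_density  2.250196  0.9565278  3.9191065              1
#> 3            wbp_area  1.138887  0.7157256  1.6119067              1
```

The generating model (cone pair + whitebark area, "M5") gets essentially
all the posterior model probability, the cone-absence coefficient is
negative (absence coded 1: sites without cones are less likely to be used)
and all three truth values (−1.5, 1.0, 0.8) are inside their 95% intervals.
Goodness of fit and a habitat threshold:

```r
posterior_predictive_gof(fit, n_draws = 300)
#> Bayesian MacKenzie-Bailey goodness-of-fit (300 draws)
#>   95% BCI of T_rep - T_obs: -15.64 to 4.28
#>   Bayesian p-value P(T_rep >= T_obs): 0.113
#>   verdict: adequate fit (BCI includes 0)

cv <- predict_psi(fit, "fall_harvest", "wbp_area")
threshold_area(cv, 0.75)
#> [1] 75869.2
```

i.e. on this synthetic landscape the posterior-mean occurrence curve
crosses 75% at about 76,000 ha of whitebark pine within the 32.6 km
foraging radius (other covariates held at their means, cones present).

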