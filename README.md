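# opennest

Estimating grassland-songbird nest density, nest survival, and
plot-scale productivity from replicated nest-search surveys with
imperfect detection.

Counting nests by dragging a rope across a prairie plot misses most of
them: the chance of detecting a chestnut-collared longspur nest on one
search is roughly 0.16, and the set of active nests changes even within
a 30-day survey window as nests fail and new ones are initiated. Raw
counts are therefore biased low, and the bias varies with habitat
(shrubby plots hide nests better). `opennest` implements the full
inference pipeline for this problem, for avian ecologists and rangeland
managers who need habitat-productivity relationships rather than raw
counts:

- **Open-population N-mixture (Dail–Madsen) model** for replicated
  counts `y_it`: latent abundance `N_i1 ~ Poisson(λ_i)` (or negative
  binomial with dispersion α), dynamics
  `N_it = Binomial(N_i,t−1, ω) + Poisson(γ)`, detection
  `y_it ~ Binomial(N_it, p_it)` with `log λ` and `logit p` linear in
  plot and survey covariates. The site likelihood is an exact forward
  recursion over latent states (Rcpp), verified against exhaustive
  trajectory enumeration.
- **Closure diagnostics**: the percent change in nest numbers per
  survey interval is `(ω + γ − 1)·100`; Wald intervals on γ and ω test
  the closure assumption. Truncation-stability checks (`K` sweeps)
  expose the identifiability pathology of the negative-binomial mixture.
- **Model selection machinery**: AICc/QAICc, Akaike weights, backward
  stepwise search (detection first, then density), a parametric
  bootstrap goodness-of-fit test with variance inflation factor ĉ, SE
  inflation, non-informative-effect screening, and model-averaged
  prediction with unconditional variances.
- **Daily nest survival (DSR)**: the exposure likelihood
  `ℓ = (a − f)·log s + [failure]·log(1 − s^(c−a))` for a nest found on
  day `f`, last active on day `a`, last checked on day `c`, with
  `logit s` linear in nest-site and plot covariates; tiered candidate
  sets at both spatial scales; period survival `s^T` with delta-method
  SE.
- **Plot-scale productivity**: empirical-Bayes (forward–backward)
  posterior of the latent nest abundance per plot, times model-averaged
  `DSR^30`, regressed on habitat and restated at management scale
  (successful nests per pasture per kg/ha of biomass).
- **Synthetic-study generator** reproducing the sampling design (100
  9-ha plots, 2–3 surveys within 30 days, shrub-dependent detection,
  correlated vegetation covariates, discovery of nests conditional on
  being active on the search day) with a full truth channel, so every
  stage is testable without field data.

## Worked example

```r
library(opennest)

# a complete synthetic study at the default design
study <- simulate_study(sim_config(), seed = 1)

# nest density: stepwise selection, bootstrap c-hat, closure test,
# empirical-Bayes abundance
den <- run_density(study$counts$data,
                   detection_terms = list("shrub"),
                   density_terms = list("biomass",
                                        c("forb", "forb^2"),
                                        c("slope", "slope^2")),
                   B = 50, seed = 1)
den$mean_detection                        # 0.133
den$closure$omega_hat                     # 0.944
den$gof$c_hat                             # 0.86

# nest survival: tiered evaluation, constant-model DSR
sur <- run_survival(study$encounters$records,
                    plot_terms = list("biomass", "forb", "litter"))
sur$null_dsr$estimate                     # 0.926
sur$period$estimate                       # 0.099  (DSR^30)
sur$apparent_success                      # 0.25   (exposure bias: > DSR^30)

# productivity: N-hat x DSR^30 per plot, regressed on biomass
prod <- run_productivity(den, sur, study$counts$data$plot_covariates)
prod$regression$slope                     # -0.000404 per kg/ha
prod$per_100_units                        # -0.040 nests per plot per +100 kg/ha
```

The numbers shown are from seed 1. Their meaning: detection averages
~0.13–0.16 per survey, so the empirical-Bayes abundance
(`den$posterior$mode`, mean 1.89) exceeds the mean raw count (0.32);
nests survive a day with probability ~0.93, hence only ~10–11% survive
the full 30-day cycle, while the apparent success of *monitored* nests
(25%) is biased upward because nests must survive long enough to be
found; and each additional 100 kg/ha of standing biomass costs about
0.04 successful nests per 9-ha plot, i.e. roughly 40 nests per 1000-ha
pasture per 1000 kg/ha.

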