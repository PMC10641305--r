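# cjsync

Bayesian multispecies Cormack-Jolly-Seber (CJS) survival estimation and
demographic-synchrony analysis for stream fish communities monitored by
bi-monthly PIT-tag mark-recapture.

The package is aimed at fish and wildlife ecologists who have encounter
histories for several species at several isolated sites, plus daily
environmental logger series, and want to know (1) which environmental
covariates drive survival, (2) how synchronous survival fluctuations are
among species within a site and between sites for the same species, and
(3) how much of the shared fluctuation the top covariate explains.

## The model

Survival between occasions is modelled on the logit scale with a
four-component temporal random-effects decomposition

logit Φ<sub>j,s,t</sub> = μ<sub>j,s</sub> + β x<sub>t</sub> +
ε1<sub>t</sub> + ε2<sub>j,t</sub> + ε3<sub>s,t</sub> + ε4<sub>j,s,t</sub>,

where ε1 ~ N(0, σ²t) is common to all species and streams, ε2 ~ N(0, σ²j)
is unique to species j, ε3 ~ N(0, σ²s) to stream s, and ε4 ~ N(0, σ²j,s)
to the combination; x<sub>t</sub> is a standardized per-interval
environmental covariate. Unequal intervals are standardized to a 60-day
basis via Φ<sup>n.days/60</sup>. Detection varies by species, stream and
occasion. The latent alive states are marginalized with the χ recursion
(χ<sub>T</sub> = 1, χ<sub>t</sub> = (1−φ<sub>t</sub>) +
φ<sub>t</sub>(1−p<sub>t+1</sub>)χ<sub>t+1</sub>), and the posterior is
sampled by an adaptive Metropolis-within-Gibbs scheme with
likelihood-invariant sweep moves (compiled core).

Synchrony for species j in stream s is the intra-class correlation

ICC = (σ²t + σ²j + σ²s) / (σ²t + σ²j + σ²s + σ²j,s),

computed per posterior draw; the covariate's synchronous-variance
contribution is σ²cov = var(β x<sub>t</sub>) with proportion
σ²cov / (σ²cov + σ²t); and pairwise Pearson correlations of the
posterior-mean survival series compare species within streams and
conspecifics between streams. Models are ranked by DIC.

## Worked example

```r
library(cjsync)

# ICC from published variance-component point estimates:
# creek chub in Indian Creek
icc_plugin(0.60, 0.44, 0.64, 0.60)
#> [1] 0.7368421   # prints as 0.74 at two decimals

# End-to-end on a synthetic study (about 2 minutes)
res <- run_pipeline(scenario_config(covariate_effect = TRUE, seed = 42),
                    settings = mcmc_settings(seed = 42),
                    out_dir = "scratch/demo")
res$report$icc
```

On the default scaled scenario (578 tagged fish) this prints, for example:

```
 species stream icc_mean icc_lower icc_upper icc_plugin
     BHC indian     0.71     0.098      1.00       0.63
     CRC indian     0.68     0.082      1.00       0.62
     STJ indian     0.54     0.038      1.00       0.52
     BHC   todd     0.75     0.160      1.00       0.71
     CRC   todd     0.34     0.015      0.99       0.25
     STJ   todd     0.56     0.051      1.00       0.53
```

posterior-mean ICCs per species-stream combination with 95% credible
intervals (wide, as expected at one-tenth of the motivating study's cohort
size), and a DIC table in which both hierarchical models beat the
intercept-only model by ~100 units. The proportion of synchronous
variation attributed to mean temperature is reported with its CRI and with
both choices of the σ²t denominator source.

## The analysis workflow

The numbered drivers under `analysis/` run the full study on synthetic
data and write tables under `results/` (large fit artifacts go to
`scratch/`):

1. `01_simulate.R` — generate the dataset (cohort table to
   `results/cohort.csv`);
2. `02_screen_covariates.R` — interval covariates and the |r| > 0.50
   collinearity screen (retains mean temperature and mean water level;
   drops the max covariates, r ≈ 0.98 with their means);
3. `03_fit_survival_models.R` — per-stream intercept/temperature/level
   model ranking by DIC and effect sizes with 95% CRIs;
4. `04_fit_synchrony_models.R` — joint intercept-only, random-effects and
   random-effects-plus-covariate fits (all R-hat < 1.1);
5. `05_synchrony_report.R` — ICC table, covariate contribution, pairwise
   correlations, DIC comparison (`results/synchrony/`).

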