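# ewlmm

Bayesian phylogenetic longitudinal mixed models for evaporative water
loss (EWL) experiments on frogs.

Amphibians lose water by evaporation across the skin and respiratory
surfaces and can regain it by absorption through the pelvic patch. Over
an hour in a dry or wet container at a controlled temperature, a frog's
body mass traces out the net balance of those fluxes. `ewlmm` is for
ecophysiologists analysing such experiments: it simulates them, applies
the standard correction/exclusion/imputation rules, and fits a
hierarchical Bayesian model that respects both the phylogenetic
relatedness of the species and the temporal autocorrelation of repeated
weighings.

## The model

Natural-log body mass is regressed on time (min), water availability
(0/1), temperature (°C, centred at 26), and ln snout–vent length
(ln mm), with species contrasts (baseline *Xenopus tropicalis*, contrasts
for *Rhinella marina* and *Phyllobates terribilis*), water × temperature
and water × time interactions — 19 fixed effects in all:

    ln m_ij = x_ij' β + u_frog + u_housing + u_date + u_species + ε_ij

Random intercepts enter for individual, housing tank, measurement date
and species; the species effects are correlated through the
Brownian-motion phylogenetic correlation matrix Φ computed from a Newick
tree sample (majority topology, mean branch lengths). Residuals of the
same animal decay in correlation as a Gaussian function of the time
difference, cor = ρ^((Δt/20)²), so ρ is directly the correlation at the
nominal 20-min weighing interval. Random effects are marginalised into a
dense Gaussian covariance and the posterior is sampled by Hamiltonian
Monte Carlo with analytic gradients (compiled core); a generalised least
squares oracle validates the sampler.

On the ln scale a time coefficient b is a 100·(exp(b)−1) percent mass
change per minute (`percent_per_minute()`), or 1000·m·(exp(b)−1) mg/min
at a reference mass m (`mass_rate()`).

## Worked example

Simulate a study-scale experiment from the published coefficient table as
ground truth, corrupt it with field artefacts, and run the full pipeline:

```r
library(ewlmm)

res <- run_pipeline(list(
  preset     = "table1",
  design     = list(study_scale = TRUE),     # 95 animals, 3 species
  corruption = list(dropout_threshold = 0.5),
  exclusion  = list(max_loss_fraction = 0.5),
  sampler    = list(chains = 2, warmup = 300, samples = 300),
  seeds      = list(simulate = 1, corrupt = 2, fit = 3)
))
res
#> <ewl_run> 380 observations, 0 excluded individuals, 0.26% missing
#>   config b0bbe3f6; 0 divergences; max R-hat 1.013

subset(res$summary, term %in% c("Time", "Water-Time", "SVL"))
#>          term          mean         q2.5         q97.5 excludes_zero
#> 2        Time -0.0015861736 -0.003184252 -0.0001191599          TRUE
#> 5         SVL  0.0598703510 -0.420431906  0.5184045117         FALSE
#> 17 Water-Time  0.0005253091 -0.001538103  0.0025452757         FALSE

marginal_temperature_effect(res$draws, "P.terribilis", water = 0)
#> P.terribilis not in water: -0.0109 ln g/degC [-0.0221, 0.0009], P(<0) = 96.50%

percent_per_minute(-0.0019)   # dehydration slope, % body mass per min
#> [1] -0.1898196
mass_rate(-0.0002, 165)       # large toad, mg per min
#> [1] -32.9967
```

The dehydration slope (`Time`) is recovered close to its simulation truth
of −0.0019 ln g/min and excludes zero; the marginal temperature effect for
*P. terribilis* is negative with high posterior probability, mirroring the
pattern the design is sensitive to. The run report carries exclusions,
missingness bookkeeping and convergence diagnostics.

The example relaxes the 20% mass-loss endpoint to 50%: under the
published error variance a quarter of simulated animals genuinely cross
20%, and the resulting censoring visibly flattens the time slope — a
selection effect worth knowing about, and easy to study by switching the
thresholds back. `parameter_recovery()` wraps the simulate–fit loop into
a coverage/bias experiment against the known truth.

A thin command-line front end with subcommands `simulate`, `prep`, `fit`,
`effects`, `recover`, `all` lives at `inst/cli/ewlmm.R`:

```sh
Rscript inst/cli/ewlmm.R all --config run.yaml --out results/
```

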