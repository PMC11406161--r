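---
title: "Modelling evaporative water loss with phylogenetic longitudinal mixed models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling evaporative water loss with phylogenetic longitudinal mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewlmm)
```

## The scientific problem

Amphibians exchange water with their environment quickly: mass lost by
evaporation across the skin and respiratory surfaces (evaporative water
loss, EWL) and mass gained by absorption through the pelvic patch can both
change a frog's body mass measurably within minutes. `ewlmm` models
short-term body-mass trajectories of frogs held with or without standing
water at two temperatures, and asks how water availability, temperature,
body size and species identity jointly shape the net rate of mass change.

The experimental template is a 2x2 design -- water presence/absence
crossed with 26 or 36 degC -- applied to three species chosen for their
contrasting ecology: the aquatic *Xenopus tropicalis*, the large
terrestrial toad *Rhinella marina*, and the terrestrial poison frog
*Phyllobates terribilis*. Each animal is weighed at treatment start and
then roughly every 20 minutes for an hour.

## The model

For observation $j$ of animal $i$, the response is natural-log body mass
(ln g):

$$\ln m_{ij} = \mathbf{x}_{ij}^\top \beta
  + u_{\mathrm{frog}(i)} + u_{\mathrm{housing}(i)}
  + u_{\mathrm{date}(i)} + u_{\mathrm{species}(i)}
  + \varepsilon_{ij}.$$

The fixed part $\mathbf{x}_{ij}^\top\beta$ has 19 terms (`ewl_terms()`):
time (min), water (0/1), temperature (degC, centred at 26), ln snout--vent
length (ln mm, centred per species), species contrasts against the
*X. tropicalis* baseline, water x temperature interactions (does standing
water blunt the thermal effect?), and water x time interactions (water
uptake is a separate time slope from dehydration). On this scale a time
coefficient $b$ means a $100(\exp b - 1)$ percent mass change per minute
(`percent_per_minute()`).

Random effects enter at four levels. Frog, housing-tank and date effects
are independent; species effects are drawn jointly with covariance
$\sigma^2_s \Phi$, where $\Phi$ is the phylogenetic correlation matrix:
under Brownian-motion trait evolution, the correlation between two species
is their shared root-to-ancestor path length divided by the geometric mean
of their root-to-tip depths (`phylo_correlation()`). $\Phi$ is computed
from a tree sample by first restricting to the majority topology and
averaging branch lengths edge-wise (`mean_branch_tree()`).

Residuals of the same animal are temporally correlated through a Gaussian
kernel in the time difference:

$$\mathrm{cor}(\varepsilon_{ij}, \varepsilon_{ik})
  = \rho^{(\Delta t_{jk}/20)^2},$$

parameterised so that $\rho$ is directly the correlation at the nominal
20-minute sampling interval; a uniform(0,1) prior then acts on an
interpretable quantity. This is algebraically the squared-exponential
kernel $\exp(-(\Delta t/\ell)^2)$ with bandwidth
$\ell = 20/\sqrt{-\log\rho}$ (`bandwidth_to_rho()` converts). Because
measurement times are jittered rather than exact, the kernel consumes the
realised time differences.

### Two readings of the composite covariance

The covariance combining phylogenetic and temporal correlation can be
assembled in two ways, both implemented in `residual_covariance()`:

* **nested** (default): the time kernel acts only within an animal's own
  residuals, and the phylogeny enters through the species random effect.
  Residual correlation between different animals -- beyond what shared
  housing, date and species induce -- is biologically implausible, which
  is why this is the default.
* **composite**: the error covariance is literally
  $\sigma^2_e \, \Phi_{s_a s_b} \, \rho^{(\Delta t/20)^2}$ for *every*
  pair of observations. This reading correlates residuals across animals
  of related species measured at similar times. It is retained for
  sensitivity analysis. Note that it is numerically much worse
  conditioned: a smooth Gaussian kernel evaluated at many clustered time
  points is nearly singular, which is exactly what the small diagonal
  nugget (1e-8) guards against.

Both modes give every observation the same marginal variance
($\sigma^2_e$ plus all applicable group variances).

### Priors

Fixed effects get normal priors assembled from a small pilot
configuration (`default_priors()`): the dehydration slope prior is centred
at a pilot loss rate (default -0.002 ln g/min), the uptake slope at minus
twice that (uptake can be up to double dehydration), and the water x
temperature interaction at a fraction of the pilot temperature effect
corresponding to the body surface shielded by standing water (one half for
the aquatic baseline, one quarter for the terrestrial species).
Body-size information enters through the ln midpoint of each species' SVL
range. Every normal sd is at least the absolute prior mean -- so zero is
always within two sd -- and never below a floor: 0.005 for rate terms,
2.0 for level terms. The level floor matters: species-level ln-mass
contrasts span several units (a 165 g toad against a 13.5 g frog is a
contrast of ~2.5 ln g), so a tight level prior would visibly shrink the
species contrasts and break parameter recovery.

Variance components get inverse-gamma priors: a narrow IG(3, 0.05) for
the error variance and a wide IG(2, 1) for each random-effect variance.
These hyperparameters are package defaults, overridable through the prior
configuration and recorded in run metadata.

### Sampling

Random effects are marginalised analytically into a dense Gaussian
covariance, so the sampler works in 25 dimensions (19 coefficients, 5 log
variances, logit $\rho$) with an exact likelihood; an explicit
random-effect formulation exists only as a validation oracle (numerical
integration on a two-frog fixture, tested to 1e-6). The likelihood and
its analytic gradient are computed in compiled code (one Cholesky and one
symmetric inverse per evaluation); `fit_hmc()` runs Hamiltonian Monte
Carlo with dual-averaging step-size adaptation (target acceptance 0.8)
and a diagonal mass matrix re-estimated midway through warmup. The
coefficient block is initialised at the GLS solution under plausible
starting variances, which removes most burn-in.

Two validation routes guard the sampler:

* with the covariance fixed and flat priors the posterior is Gaussian
  with mean equal to the GLS estimate (`gls_fit()`); the HMC means must
  match within Monte Carlo error;
* a parameter-recovery experiment (`parameter_recovery()`) simulates
  replicate experiments at study scale from the published coefficient
  table as truth and checks 95% credible-interval coverage of all 19
  coefficients and near-zero bias of the dehydration and uptake slopes.

Desk-scale sampler geometry is deliberately small: the recovery
experiment uses 2 chains x 200 warmup / 200 samples with ~5 leapfrog
steps per iteration (roughly half a minute per replicate at 380
observations), and package examples use similar sizes. The study-scale
geometry (4 chains, 30,000 warmup, 50,000 samples) is available through
the same configuration surface when compute allows.

## The synthetic-data generator

`make_design()` lays out animals the way the experiment was run: one
animal per treatment per measurement date (4 per date), dates accumulating
until each species' quota is filled, housing tanks alternating within
species, SVL uniform within the species range. `study_design()` gives the
study's 95 animals (32/32/31). `simulate_experiment()` then draws the four
random-effect sources once (species jointly with $\Phi$), jitters the
nominal {0, 20, 40, 60} min schedule by +/-3 min, and generates ln-mass
trajectories from the linear predictor plus kernel-correlated residuals.
Starting masses are derived from SVL through the same coefficients the
model estimates, so simulation truth and fitted coefficients align by
construction.

`corrupt_series()` adds the field artefacts the preprocessing rules
exist for: a single urination/defecation event per affected animal
(0.5--3% of current body mass, subtracted from that weighing onward and
recorded), truncation of measurements after cumulative observed loss
exceeds 20% (the welfare endpoint), and sporadic masking of interior
weighings. `corrupt_experiment()` can instead mask an exact total count,
which makes missingness bookkeeping exactly checkable.

What the generator does *not* emulate: behavioural avoidance (animals
climbing out of the water), humidity variation, scale drift, or any
relation between righting-response failure and mass loss beyond the 20%
rule -- there is no quantitative handle on these. Passing
recovery tests therefore demonstrates correctness of the inference
machinery under the model's own assumptions, not robustness to these
unmodelled features of real data.

A note on scale: the published coefficient table is used as-is for the
`"table1"` truth preset, including its intercept (0.0887 ln g), whose
centring the source does not state. Simulated masses are therefore
internally consistent with the coefficients rather than matched to
field-realistic masses per species; nothing downstream depends on the
absolute scale.

One temporal parameter is not published: the residual correlation at the
20-min lag. All presets use $\rho = 0.5$, a moderate decay over one
sampling interval, and the recovery experiment treats it as a parameter
to estimate like any other.

## Preprocessing rules

`correct_excretion()` adds recorded excreted mass back to the weighing at
which it was noticed and all later ones (cumulatively), since that mass
loss is not evaporative. `impute_missing()` implements the two rules used
for the study's 18 missing weighings: per-animal linear regression of
mass on time, and the adjacent mean for an interior gap with a measured
value on each side; `impute_series()` applies the adjacent rule exactly
to interior single gaps and regression everywhere else.
`apply_exclusions()` removes animals that lost more than 20% of starting
mass (or carry a manual flag, e.g. no righting response) and reports each
removal with its reason.

The regression rule is fit per individual. Pooling all animals would mix
species with order-of-magnitude mass differences, so the per-individual
fit is the only defensible reading; a pooled option exists behind the
configuration for sensitivity analysis.

Coding defaults: water 0/1 with the no-water baseline, temperature
centred at 26 degC (the intercept then refers to the cooler treatment;
with only two levels the temperature slope is the 10-degree contrast
divided by 10, and extrapolation beyond 26--36 degC is not supported by
the design), time in minutes from treatment start, ln SVL centred at the
ln midpoint of the species' SVL range. The midpoint centring (rather than
the within-sample species mean) is deliberate: it is data-independent, so
the intercept means the same thing across datasets and the generator's
truth coefficients are exactly the estimands of the fitted model. The
sample-mean centring remains available via
`ewl_coding(svl_center = "species_mean")`.

## Numerical choices

* Covariance nugget 1e-8 on the diagonal: keeps the matrix invertible
  when two measurements coincide in time and in the near-singular
  composite mode.
* Step-size adaptation uses the standard dual-averaging constants
  ($\gamma = 0.05$, $t_0 = 10$, $\kappa = 0.75$); leapfrog counts are
  jittered +/-20% to avoid periodicity.
* Divergences are flagged when the Hamiltonian error exceeds 50; a
  divergence fraction above 5% is reported as a warning in the
  diagnostics, never an exception.
* Ties in `prob_direction()` count one half -- immaterial for continuous
  draws, stated for determinism.
* Variance ratios are reported with a nearest-integer rendering alongside
  the exact ratio.
* `classify_outcome()` works on credible intervals, not point slopes: the
  water effect is absent (O2) when the in/out-of-water slope intervals
  overlap, and the temperature interaction is absent (O1/O4) when the
  36-minus-26 slope contrast interval covers zero, with the contrast
  interval formed by Gaussian combination of the per-condition interval
  half-widths.

## Known limitations

* With one animal per species x treatment cell the design is structurally
  singular (ln SVL is then constant within cells); at least two animals
  per cell are required.
* Only two temperature levels exist, so the temperature "slope" is a
  two-point contrast; the model cannot detect curvature in temperature.
* The species variance is informed by three species; its posterior is
  prior-sensitive by necessity, and the frog-level variance and kernel
  correlation are only weakly separable with four measurements per
  animal. The fixed-effect coefficients, which the scientific questions
  concern, are insensitive to this.
* The composite covariance mode is retained for sensitivity analysis but
  is near-singular by construction at realistic designs; conclusions
  should rest on the nested mode.
* Under the published coefficient table as truth, the residual sd
  (~0.13 ln g per weighing) makes roughly a quarter of simulated animals
  cross the 20% loss endpoint, and the resulting censoring visibly
  flattens the estimated time slope in end-to-end pipeline runs. The real
  study removed far fewer animals, so its error variance evidently
  absorbs more than weighing noise. The parameter-recovery experiment
  therefore runs the clean generator without exclusions — it validates
  the inference machinery, not the exclusion rule — and pipeline users
  studying slope estimates should treat the exclusion threshold as part
  of the data-generating story, not a neutral cleaning step.
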