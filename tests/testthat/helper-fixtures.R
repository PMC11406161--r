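# Shared fixtures, built in code.

# Truth with all random variation switched off and a chosen set of slopes;
# remaining coefficients zero unless supplied.
deterministic_truth <- function(..., rho = 0.5) {
  beta <- stats::setNames(numeric(19), ewl_terms())
  override <- list(...)
  beta[names(override)] <- unlist(override)
  ewl_truth(beta, c(frog = 0, housing = 0, date = 0, species = 0,
                    error = 0), rho)
}

# One X. tropicalis individual at the SVL range midpoint (so the centred
# ln SVL term vanishes), 26 degC.
baseline_individual <- function(water = 0, temp_c = 26, id = "frog-01") {
  list(id = id, species = "X.tropicalis", svl_mm = 34, water = water,
       temp_c = temp_c, housing = "X.tropicalis-H1", date = "d01")
}

# Small design + simulated experiment for model-fitting tests.
small_experiment <- function(n_per_treatment = 2, preset = "table1",
                             seed = 101) {
  design <- make_design(n_per_treatment, seed = seed)
  truth <- truth_parameters(preset)
  ex <- simulate_experiment(design, truth, seed = seed + 1)
  list(design = design, truth = truth, experiment = ex,
       frame = build_model_frame(ex$series, design))
}

# A 3-tip tree matching the study clade structure.
toy_tree <- function(text = "((A:1,B:1):1,C:2);") ape::read.tree(text = text)
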