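# Shared fixtures: all built in code at test time.

# Parameter set with every rate zero except those supplied; Ea = 0 makes
# the constants temperature-independent, which keeps closed-form oracles
# exact at any storage temperature.
bare_params <- function(..., kHp = 0.025, k8 = 0) {
  k <- setNames(rep(0, 7), paste0("k", 1:7))
  over <- c(...)
  k[names(over)] <- over
  kinetic_parameters(k_ref = k, Ea = setNames(rep(0, 7), paste0("Ea", 1:7)),
                     k8 = k8, kHp = kHp)
}

# Fixed measured-pH condition (linear subsystem: ion concentrations are
# constants of the trajectory).
measured_env <- function(pH = 7, temp_C = 40, aw = 0.10,
                         ratio = 1.0, peg_hpmc = 0.5) {
  stability_condition(temp_C, aw, ratio, peg_hpmc,
                      ph_mode = "measured", ph_measured = pH)
}

dynamic_env <- function(temp_C = 40, aw = 0.10, ratio = 1.4) {
  comp <- make_initial_composition(ratio)
  stability_condition(temp_C, aw, ratio, comp$peg_hpmc_ratio)
}

# Noiseless full-factorial study under the default truth, generated once
# per test run and cached (used by several files).
.fixture_cache <- new.env(parent = emptyenv())
noiseless_full_study <- function() {
  if (is.null(.fixture_cache$full)) {
    .fixture_cache$full <- generate_study(study_design(sigma = 0, seed = 42))
  }
  .fixture_cache$full
}

# Small reduced-design study for fitting tests: 2 compositions x 2
# temperatures x 1 humidity, 5 time points.
reduced_design <- function(sigma = 0, seed = 7, temps_C = c(40, 50)) {
  study_design(peg_saxa_ratios = c(0.8, 1.4), temps_C = temps_C, aw = 0.10,
               times = c(0, 14, 45, 90, 180), sigma = sigma, seed = seed)
}

# Random non-negative species state (for conservation / homogeneity loops).
random_state <- function() {
  v <- runif(9, 0, 1)
  do.call(species_state, as.list(setNames(v, SPECIES)))
}
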