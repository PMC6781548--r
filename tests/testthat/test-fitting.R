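test_that("residuals follow the range-weighted definition", {
  # zero-rate model: prediction stays at the initial state
  env <- measured_env(pH = 7, ratio = 1, peg_hpmc = 0.5)
  d <- stability_dataset(
    "one", env, initial_composition(0, 2.0),
    data.frame(time_days = 7, species = "SAXA", value = 1.0,
               below_loq = 0L))
  r <- kinetic_residuals(bare_params(), list(d),
                         weights = c(SAXA = 2.0))
  expect_equal(r, 0.5)                       # (2 - 1) / 2
  # default weights are the per-species maxima across datasets
  expect_equal(unname(species_weights(list(d))["SAXA"]), 1.0)
})

test_that("observations from the simulator give a zero residual vector", {
  study <- generate_study(reduced_design(sigma = 0))
  r <- kinetic_residuals(default_parameters(), study)
  expect_equal(max(abs(r)), 0)
})

test_that("below-LOQ observations penalize one-sidedly", {
  env <- measured_env(pH = 7, ratio = 1, peg_hpmc = 0.5)
  d <- stability_dataset(
    "cens", env, initial_composition(0, 1.0),
    data.frame(time_days = c(7, 7), species = c("SCA", "SAXA"),
               value = c(0.01, 1.0), below_loq = c(1L, 0L)),
    loq = c(SCA = 0.01))
  # zero rates: simulated SCA = 0 < LOQ -> exactly no contribution
  r <- kinetic_residuals(bare_params(), list(d))
  expect_equal(r, c(0, 0))
  # simulated above the LOQ: one-sided excess is penalized
  p <- bare_params(k5 = 2e5)                 # k_eff 0.02/day
  r2 <- kinetic_residuals(p, list(d), weights = c(SCA = 1, SAXA = 1))
  sim_sca <- 1 - exp(-0.02 * 7)
  expect_equal(r2[1], sim_sca - 0.01, tolerance = 1e-6)
})

test_that("residual SSE is invariant under dataset and row permutation", {
  study <- generate_study(reduced_design(sigma = 0.05))
  p <- default_parameters()
  sse <- sum(kinetic_residuals(p, study)^2)
  study_rev <- rev(study)
  set.seed(3)
  study_rev <- lapply(study_rev, function(d) {
    d$observations <- d$observations[sample(nrow(d$observations)), ]
    d
  })
  expect_equal(sum(kinetic_residuals(p, study_rev)^2), sse)
})

test_that("a fit started at the optimum stays there", {
  study <- generate_study(reduced_design(sigma = 0))
  truth <- default_parameters()
  fit <- fit_kinetics(truth, study, free = "k5")
  expect_true(fit$converged)
  expect_lte(fit$iterations, 2L)
  expect_lt(fit$residual_sum, 1e-16)
  expect_equal(fit$params$k_ref[["k5"]], 1.6e5, tolerance = 1e-8)
})

test_that("noiseless joint recovery of cyclization parameters is exact", {
  study <- generate_study(reduced_design(sigma = 0))
  truth <- default_parameters()
  start <- default_parameters()
  start$k_ref[["k5"]] <- truth$k_ref[["k5"]] * 1.5
  start$Ea[["Ea5"]] <- truth$Ea[["Ea5"]] * 1.5
  fit <- fit_kinetics(start, study, free = c("k5", "Ea5"))
  expect_true(fit$converged)
  expect_equal(fit$params$k_ref[["k5"]], truth$k_ref[["k5"]],
               tolerance = 1e-2)
  expect_equal(fit$params$Ea[["Ea5"]], truth$Ea[["Ea5"]], tolerance = 1e-2)
  # recovery error shrinks (or stays flat) as integration tightens
  coarse <- fit_kinetics(start, study, free = c("k5", "Ea5"), tol = 1e-2,
                         dt_init = 16)
  err_c <- abs(coarse$params$Ea[["Ea5"]] - truth$Ea[["Ea5"]])
  err_f <- abs(fit$params$Ea[["Ea5"]] - truth$Ea[["Ea5"]])
  expect_lte(err_f, err_c + 1e-8)
})

test_that("median recovery under 5% noise stays within 10%", {
  truth <- default_parameters()
  errs <- vapply(c(101, 202, 303), function(seed) {
    study <- generate_study(reduced_design(sigma = 0.05, seed = seed))
    start <- truth
    start$k_ref[["k5"]] <- truth$k_ref[["k5"]] * 1.5
    start$Ea[["Ea5"]] <- truth$Ea[["Ea5"]] * 1.5
    fit <- fit_kinetics(start, study, free = c("k5", "Ea5"))
    abs(fit$params$Ea[["Ea5"]] - truth$Ea[["Ea5"]]) / truth$Ea[["Ea5"]]
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("freezing a recovered parameter does not degrade the fit", {
  study <- generate_study(reduced_design(sigma = 0.05, seed = 5))
  start <- default_parameters()
  start$k_ref[["k5"]] <- start$k_ref[["k5"]] * 1.3
  start$Ea[["Ea5"]] <- start$Ea[["Ea5"]] * 1.3
  fit <- fit_kinetics(start, study, free = c("k5", "Ea5"))
  refit <- fit_kinetics(fit$params, study, free = "Ea5")
  expect_lte(refit$residual_sum,
             fit$residual_sum + 1e-12 * max(1, fit$residual_sum))
})

test_that("staged and direct joint fits agree on noiseless data", {
  design <- study_design(peg_saxa_ratios = c(0.8, 1.4), temps_C = c(40, 50),
                         aw = 0.10, times = c(0, 14, 45, 90, 180),
                         sigma = 0, seed = 9)
  study <- generate_study(design)
  truth <- default_parameters()
  free <- c("k5", "k7", "kHp", "Ea5", "Ea7")
  start <- set_free_params(truth,
                           setNames(get_free_params(truth, free) * 1.5,
                                    free))
  staged <- fit_sequence(study, start, free_k = c("k5", "k7", "kHp"),
                         free_Ea = c("Ea5", "Ea7"))
  joint <- fit_kinetics(start, study, free = free)
  expect_true(staged$converged)
  expect_true(joint$converged)
  vs <- get_free_params(staged$params, free)
  vj <- get_free_params(joint$params, free)
  expect_equal(vs, vj, tolerance = 1e-3)
})

test_that("single-temperature data cannot constrain activation energies", {
  design <- study_design(peg_saxa_ratios = c(0.8, 1.4), temps_C = 40,
                         aw = 0.10, times = c(0, 14, 45, 90), sigma = 0)
  study <- generate_study(design)
  res <- fit_sequence(study, default_parameters(), free_Ea = c("Ea5"))
  expect_false(res$converged)
  expect_match(res$message, "non-identifiable")
})

test_that("staged fit requires its starting block and reports failures", {
  design <- study_design(peg_saxa_ratios = 1.0, temps_C = c(30, 50),
                         aw = 0.30, times = c(0, 14, 45, 90), sigma = 0)
  study <- generate_study(design)
  expect_error(fit_sequence(study, default_parameters()),
               "40 degC / aw 0.10")
  # simulation failure propagates the offending condition id
  expect_error(
    kinetic_residuals(default_parameters(), study, tol = 1e-18,
                      max_halvings = 3L),
    "R1.0_T30_RH30")
  # log-space start must be positive
  expect_error(fit_kinetics(bare_params(), study, free = "k5"),
               "strictly positive")
})

test_that("study tables and parameter files round-trip through disk", {
  study <- generate_study(reduced_design(sigma = 0.05, seed = 13))
  obs <- withr::local_tempfile(fileext = ".csv")
  cond <- withr::local_tempfile(fileext = ".csv")
  write_study_csv(study, obs, cond)
  back <- read_study_csv(obs, cond)
  expect_length(back, length(study))
  expect_equal(back[[1]]$observations$value, study[[1]]$observations$value,
               tolerance = 1e-12)
  expect_equal(back[[1]]$env$temp_C, study[[1]]$env$temp_C)
  expect_equal(back[[1]]$init$c_peg_tot_0, study[[1]]$init$c_peg_tot_0,
               tolerance = 1e-12)
  pj <- withr::local_tempfile(fileext = ".json")
  write_params_json(default_parameters(), pj)
  p2 <- read_params_json(pj)
  expect_equal(p2$k_ref, default_parameters()$k_ref)
  expect_equal(p2$Ea, default_parameters()$Ea)
  expect_equal(p2$kHp, default_parameters()$kHp)
})
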