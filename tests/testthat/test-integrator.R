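test_that("zero rates give a constant trajectory at the grid points", {
  env <- dynamic_env()
  init <- initial_composition(5, 0.8)
  traj <- simulate_kinetics(init, bare_params(), env, c(0, 7, 50, 200))
  expect_equal(nrow(traj$states), 4L)
  for (i in 2:4) expect_equal(traj$states[i, ], traj$states[1, ])
  expect_equal(unname(traj$states[1, "SAXA"]), 0.8)
  expect_equal(unname(traj$states[1, "PEG"]), traj$x_peg * 5)
})

test_that("single-reaction decay matches the exponential closed form", {
  env <- measured_env(pH = 7)
  p <- bare_params(k5 = 2e5)           # k_eff = 2e5 * 1e-7 = 0.02 / day
  init <- initial_composition(0, 0.79)
  t_grid <- seq(0, 200, by = 10)
  traj <- simulate_kinetics(init, p, env, t_grid)
  expected <- 0.79 * exp(-0.02 * t_grid)
  expect_equal(unname(traj$states[, "SAXA"]), expected, tolerance = 1e-6)
  expect_equal(unname(traj$states[, "SCA"]), 0.79 - expected,
               tolerance = 1e-6)
})

test_that("serial cyclization matches the Bateman closed form", {
  env <- measured_env(pH = 7)
  p <- bare_params(k5 = 2e5, k6 = 5e5)  # k_eff 0.02 and 0.05 / day
  init <- initial_composition(0, 1)
  t_grid <- seq(0, 200, by = 5)
  traj <- simulate_kinetics(init, p, env, t_grid)
  ka <- 0.02; kb <- 0.05
  bateman <- ka / (kb - ka) * (exp(-ka * t_grid) - exp(-kb * t_grid))
  expect_equal(unname(traj$states[, "SCA"]), bateman, tolerance = 1e-6)
  esca <- 1 - exp(-ka * t_grid) - bateman
  expect_equal(unname(traj$states[, "ESCA"]), esca, tolerance = 1e-6)
})

test_that("family totals drift below 1e-8 relative over 200 days", {
  env <- dynamic_env(temp_C = 50, aw = 0.5)
  comp <- make_initial_composition(1.4)
  traj <- simulate_kinetics(comp$init, default_parameters(), env,
                            seq(0, 200, by = 5))
  tot <- t(apply(traj$states, 1, function(r) {
    family_totals(structure(r, names = SPECIES))
  }))
  for (fam in c("saxa_family", "peg_family")) {
    drift <- abs(tot[, fam] - tot[1, fam]) / tot[1, fam]
    expect_lt(max(drift), 1e-8)
  }
})

test_that("halving the converged step moves no concentration above tol", {
  env <- dynamic_env()
  comp <- make_initial_composition(1.2)
  p <- default_parameters()
  grid <- c(0, 7, 14, 30, 60, 108, 180)
  t1 <- simulate_kinetics(comp$init, p, env, grid, tol = 1e-5)
  t2 <- simulate_kinetics(comp$init, p, env, grid, tol = 1e-5,
                          dt_init = t1$dt / 2)
  expect_lt(max(abs(t1$states - t2$states)), 1e-5)
})

test_that("trajectories are invariant under output-grid refinement", {
  env <- dynamic_env()
  comp <- make_initial_composition(1.0)
  p <- default_parameters()
  coarse <- c(0, 30, 60, 120, 180)
  fine <- sort(unique(c(coarse, 13, 45, 97, 151)))
  tc <- simulate_kinetics(comp$init, p, env, coarse)
  tf <- simulate_kinetics(comp$init, p, env, fine)
  shared <- match(coarse, fine)
  expect_lt(max(abs(tc$states - tf$states[shared, ])), 1e-10)
})

test_that("solution agrees with an independent stiff solver", {
  skip_if_not_installed("deSolve")
  env <- dynamic_env(temp_C = 50, aw = 0.3)
  comp <- make_initial_composition(1.4)
  p <- default_parameters()
  grid <- c(0, 7, 30, 90, 180)
  traj <- simulate_kinetics(comp$init, p, env, grid)
  y0 <- traj$states[1, ]
  rhs <- function(t, y, parms) {
    list(unname(ode_rhs(structure(pmax(y, 0), names = SPECIES), p, env)))
  }
  ref <- deSolve::lsoda(y0, grid, rhs, NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(traj$states), unname(ref[, -1]), tolerance = 1e-6)
})

test_that("formaldehyde peaks only when consumption follows production", {
  env <- dynamic_env()
  comp <- make_initial_composition(1.4)
  grid <- seq(0, 180, by = 2)
  # production only: monotone non-decreasing, no interior maximum
  t_noox <- simulate_kinetics(comp$init, bare_params(k3 = 0.06), env, grid)
  expect_null(formaldehyde_peak(t_noox))
  # production + consumption with a finite PEG pool: interior maximum,
  # located where a dense grid scan of the same trajectory puts it
  t_both <- simulate_kinetics(comp$init, default_parameters(), env, grid)
  pk <- formaldehyde_peak(t_both)
  expect_false(is.null(pk))
  dense <- simulate_kinetics(comp$init, default_parameters(), env,
                             seq(0, 180, by = 0.5))
  scan <- dense$times[which.max(dense$states[, "F"])]
  expect_lt(abs(pk$t_max - scan), 2)
  expect_gt(pk$c_F_max, 0)
  # no PEG: formaldehyde identically zero
  t_zero <- simulate_kinetics(initial_composition(0, 0.79),
                              default_parameters(), env, grid)
  expect_null(formaldehyde_peak(t_zero))
})

test_that("invalid grids and exhausted refinement raise errors", {
  env <- dynamic_env()
  init <- make_initial_composition(1)$init
  p <- default_parameters()
  expect_error(simulate_kinetics(init, p, env, c(5, 10)), "start at 0")
  expect_error(simulate_kinetics(init, p, env, c(0, 10, 10)),
               "strictly increasing")
  expect_error(
    simulate_kinetics(init, p, env, c(0, 30), tol = 1e-18,
                      max_halvings = 3L),
    "failed to converge")
})

test_that("trajectory writer emits the fixed column layout", {
  env <- dynamic_env()
  comp <- make_initial_composition(1)
  traj <- simulate_kinetics(comp$init, default_parameters(), env,
                            c(0, 30, 90))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  got <- read.csv(path)
  expect_identical(names(got),
                   c("time_days", SPECIES, "pH", "x_PEG"))
  expect_equal(got$SAXA, unname(traj$states[, "SAXA"]), tolerance = 1e-12)
})
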