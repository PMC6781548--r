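# Multi-condition regression of kinetic parameters against stability data.
#
# The loss is a weighted least-squares over all observations, with
# per-species range weights (the maximum observed value of each species
# across all datasets) so that ppm-scale PEG impurities and the
# percent-scale drug assay contribute comparably, and one-sided handling of
# below-LOQ observations: a censored point only penalizes predictions that
# exceed the quantitation limit. Minimization is Levenberg-Marquardt
# (minpack.lm) on log-transformed parameters, which enforces positivity
# without explicit bounds.

#' Stability dataset for one storage condition
#'
#' @param condition_id Short identifier string.
#' @param env A [stability_condition()].
#' @param init An [initial_composition()].
#' @param observations Data frame with columns `time_days`, `species`,
#'   `value` (mol/kg; pH rows in pH units), `below_loq` (0/1). Censored
#'   rows store the LOQ as `value` with the flag set.
#' @param loq Named numeric, LOQ per species, mol/kg.
#' @return Object of class `stability_dataset`.
#' @export
stability_dataset <- function(condition_id, env, init, observations,
                              loq = numeric()) {
  stopifnot(inherits(env, "stability_condition"),
            inherits(init, "initial_composition"),
            is.data.frame(observations))
  need <- c("time_days", "species", "value", "below_loq")
  if (!all(need %in% names(observations))) {
    stop("observations must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(observations$value < 0)) {
    stop("observed values must be >= 0", call. = FALSE)
  }
  structure(list(condition_id = condition_id, env = env, init = init,
                 observations = observations, loq = loq),
            class = "stability_dataset")
}

#' Per-species range weights across datasets
#'
#' @param datasets List of [stability_dataset()].
#' @return Named numeric, maximum observed value per species (1 where the
#'   maximum is 0, so empty series stay well-defined).
#' @export
species_weights <- function(datasets) {
  obs <- do.call(rbind, lapply(datasets, function(d) {
    d$observations[c("species", "value")]
  }))
  w <- tapply(obs$value, obs$species, max)
  w[w <= 0] <- 1
  w <- c(w)
  w
}

# Free-parameter plumbing: parameters are addressed by the names
# k1..k7 (reference rates), Ea1..Ea7, k8, kHp.
free_param_names <- function() {
  c(paste0("k", 1:7), paste0("Ea", 1:7), "k8", "kHp")
}

get_free_params <- function(params, free) {
  vapply(free, function(nm) {
    if (nm %in% paste0("k", 1:7)) params$k_ref[[nm]]
    else if (nm %in% paste0("Ea", 1:7)) params$Ea[[nm]]
    else if (nm == "k8") params$k8
    else if (nm == "kHp") params$kHp
    else stop("unknown parameter name: ", nm, call. = FALSE)
  }, numeric(1))
}

set_free_params <- function(params, values) {
  for (nm in names(values)) {
    v <- values[[nm]]
    if (nm %in% paste0("k", 1:7)) params$k_ref[[nm]] <- v
    else if (nm %in% paste0("Ea", 1:7)) params$Ea[[nm]] <- v
    else if (nm == "k8") params$k8 <- v
    else if (nm == "kHp") params$kHp <- v
    else stop("unknown parameter name: ", nm, call. = FALSE)
  }
  params
}

#' Weighted residual vector over stability datasets
#'
#' Simulates each dataset's condition under `params` and returns, for every
#' observation, `(simulated - observed) / w_s` with `w_s` the species range
#' weight; below-LOQ observations contribute the one-sided penalty
#' `max(0, simulated - LOQ) / w_s`. pH observations are compared against
#' the trajectory's derived pH series.
#'
#' @param params A [kinetic_parameters()].
#' @param datasets List of [stability_dataset()].
#' @param weights Optional named species weights; defaults to
#'   [species_weights()] of `datasets`.
#' @param tol,dt_init,max_halvings Integrator settings, see
#'   [simulate_kinetics()].
#' @return Numeric residual vector, one element per observation.
#' @export
kinetic_residuals <- function(params, datasets, weights = NULL,
                              tol = 1e-5, dt_init = 1, max_halvings = 20L) {
  if (is.null(weights)) weights <- species_weights(datasets)
  res <- lapply(datasets, function(d) {
    obs <- d$observations
    t_grid <- sort(unique(c(0, obs$time_days)))
    traj <- tryCatch(
      simulate_kinetics(d$init, params, d$env, t_grid, tol = tol,
                        dt_init = dt_init, max_halvings = max_halvings),
      error = function(e) {
        stop("simulation failed for condition '", d$condition_id, "': ",
             conditionMessage(e), call. = FALSE)
      })
    idx <- match(obs$time_days, t_grid)
    sim <- numeric(nrow(obs))
    is_ph <- obs$species == "pH"
    if (any(is_ph)) sim[is_ph] <- traj$pH[idx[is_ph]]
    if (any(!is_ph)) {
      sim[!is_ph] <- traj$states[cbind(idx[!is_ph],
                                       match(obs$species[!is_ph], SPECIES))]
    }
    w <- unname(weights[obs$species])
    w[is.na(w) | w <= 0] <- 1
    cens <- obs$below_loq == 1
    r <- (sim - obs$value) / w
    if (any(cens)) {
      loq <- unname(d$loq[obs$species[cens]])
      loq[is.na(loq)] <- obs$value[cens][is.na(loq)]
      r[cens] <- pmax(0, sim[cens] - loq) / w[cens]
    }
    r
  })
  unlist(res, use.names = FALSE)
}

#' Levenberg-Marquardt fit of kinetic parameters
#'
#' Minimizes the weighted residual vector of [kinetic_residuals()] over the
#' parameters named in `free` (all others frozen at their values in
#' `params_init`). Free parameters are optimized in log-space, so they must
#' be strictly positive at the start. Convergence follows the
#' Levenberg-Marquardt criteria with relative tolerances of 1e-10 on the
#' sum of squares and on the step norm, up to `maxiter` iterations;
#' non-convergence is reported in the result, not raised.
#'
#' @param params_init Starting [kinetic_parameters()].
#' @param datasets List of [stability_dataset()]; at least one.
#' @param free Character vector of parameter names to fit, from
#'   `k1..k7`, `Ea1..Ea7`, `k8`, `kHp`.
#' @param weights Optional species weights (default: range weights).
#' @param tol,dt_init Integrator settings used inside the loss.
#' @param maxiter Maximum LM iterations (default 500).
#' @return Object of class `kin_fit`: fitted `params`, `residual_sum`,
#'   `n_obs`, `n_params`, `converged`, `iterations`, `info`, `message`,
#'   `free`, and `history` (natural-space parameter values at each residual
#'   evaluation).
#' @export
fit_kinetics <- function(params_init, datasets, free, weights = NULL,
                         tol = 1e-5, dt_init = 1, maxiter = 500L) {
  stopifnot(length(datasets) >= 1L, length(free) >= 1L)
  bad <- setdiff(free, free_param_names())
  if (length(bad)) stop("unknown free parameters: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(weights)) weights <- species_weights(datasets)
  start <- get_free_params(params_init, free)
  if (any(start <= 0)) {
    stop("free parameters must be strictly positive at the start ",
         "(log-space optimization): ",
         paste(free[start <= 0], collapse = ", "), call. = FALSE)
  }
  history <- list()
  fn <- function(theta) {
    vals <- exp(theta)
    names(vals) <- free
    history[[length(history) + 1L]] <<- vals
    p <- set_free_params(params_init, vals)
    kinetic_residuals(p, datasets, weights = weights, tol = tol,
                      dt_init = dt_init)
  }
  r0 <- fn(log(start))
  if (any(!is.finite(r0))) {
    stop("non-finite residuals at the starting parameters", call. = FALSE)
  }
  lm <- minpack.lm::nls.lm(
    par = log(start), fn = fn,
    control = minpack.lm::nls.lm.control(
      ftol = 1e-10, ptol = 1e-10, maxiter = maxiter))
  best <- exp(lm$par)
  names(best) <- free
  params <- set_free_params(params_init, best)
  n_obs <- sum(vapply(datasets, function(d) nrow(d$observations), integer(1)))
  structure(list(
    params = params,
    residual_sum = lm$deviance,
    n_obs = n_obs,
    n_params = length(free),
    converged = lm$info %in% 1:4,
    iterations = lm$niter,
    info = lm$info,
    message = lm$message,
    free = free,
    history = do.call(rbind, history)
  ), class = "kin_fit")
}

#' @export
print.kin_fit <- function(x, ...) {
  cat("Kinetic fit:", x$n_params, "free parameters,", x$n_obs,
      "observations\n")
  cat("converged:", x$converged, "(", trimws(x$message), ") after",
      x$iterations, "iterations; weighted SSE =",
      format(x$residual_sum, digits = 6), "\n")
  print(get_free_params(x$params, x$free))
  invisible(x)
}

#' Staged multi-condition fit
#'
#' Mirrors the model-building sequence used for the original study: (1) the
#' apparent rate constants (and the humidity proportionality) are regressed
#' on the 40 degC / a_w 0.10 block alone — in the reference-rate
#' parameterization this stage is independent of the activation energies;
#' (2) with the rates frozen, `kHp` is refit on the remaining 40 degC
#' humidities; (3) the activation energies in `free_Ea` are regressed
#' across all temperatures, initialized from the earlier stages. The final
#' joint result over all datasets is returned, with the per-stage fits
#' attached.
#'
#' @param datasets List of [stability_dataset()]; must contain the
#'   40 degC / a_w 0.10 block.
#' @param params_init Starting [kinetic_parameters()].
#' @param free_k Stage-1 free parameters (default `k1..k7` and `kHp`).
#' @param free_Ea Stage-3 free activation energies (default `Ea1..Ea7`).
#' @param weights,tol,dt_init,maxiter Passed to [fit_kinetics()].
#' @return A `kin_fit` with element `stages` (list of the stage fits).
#'   Single-temperature data with activation energies free is flagged
#'   non-identifiable: the result has `converged = FALSE` and a diagnostic
#'   message, since one temperature cannot separate a pre-exponential
#'   factor from its activation energy.
#' @export
fit_sequence <- function(datasets, params_init = default_parameters(),
                         free_k = c(paste0("k", 1:7), "kHp"),
                         free_Ea = paste0("Ea", 1:7),
                         weights = NULL, tol = 1e-5, dt_init = 1,
                         maxiter = 500L) {
  temps <- vapply(datasets, function(d) d$env$temp_C, numeric(1))
  aws <- vapply(datasets, function(d) d$env$aw, numeric(1))
  stage1_sel <- abs(temps - 40) < 0.5 & abs(aws - 0.10) < 0.005
  if (!any(stage1_sel)) {
    stop("staged fit requires the 40 degC / aw 0.10 block", call. = FALSE)
  }
  if (length(free_Ea) > 0 && length(unique(temps)) < 2L) {
    res <- structure(list(
      params = params_init, residual_sum = NA_real_,
      n_obs = sum(vapply(datasets, function(d) nrow(d$observations),
                         integer(1))),
      n_params = length(free_Ea), converged = FALSE, iterations = 0L,
      info = NA_integer_,
      message = paste("non-identifiable: activation energies cannot be",
                      "regressed from a single temperature"),
      free = free_Ea, history = NULL, stages = list()
    ), class = "kin_fit")
    return(res)
  }
  if (is.null(weights)) weights <- species_weights(datasets)
  stages <- list()
  p <- params_init
  if (length(free_k) > 0) {
    stages$rates_40C <- fit_kinetics(p, datasets[stage1_sel], free_k,
                                     weights = weights, tol = tol,
                                     dt_init = dt_init, maxiter = maxiter)
    p <- stages$rates_40C$params
  }
  stage2_sel <- abs(temps - 40) < 0.5 & !stage1_sel
  if (any(stage2_sel) && "kHp" %in% free_k) {
    stages$humidity <- fit_kinetics(p, datasets[stage2_sel], "kHp",
                                    weights = weights, tol = tol,
                                    dt_init = dt_init, maxiter = maxiter)
    p <- stages$humidity$params
  }
  if (length(free_Ea) > 0) {
    stages$arrhenius <- fit_kinetics(p, datasets, free_Ea,
                                     weights = weights, tol = tol,
                                     dt_init = dt_init, maxiter = maxiter)
    p <- stages$arrhenius$params
  }
  final <- stages[[length(stages)]]
  final$params <- p
  final$residual_sum <- sum(kinetic_residuals(p, datasets,
                                              weights = weights, tol = tol,
                                              dt_init = dt_init)^2)
  final$n_obs <- sum(vapply(datasets, function(d) nrow(d$observations),
                            integer(1)))
  final$stages <- stages
  final
}
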