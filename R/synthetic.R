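# Synthetic stability-study generator. Emulates the factorial accelerated
# stability design the model was built on: four film-coat compositions
# (PEG:SAXA 0.8-1.4 with matched PEG:HPMC ratios), storage at 30/40/50 degC
# after pre-equilibration to water activities 0.10/0.30/0.50, sampling from
# day 7 to about day 108 with longer simulated horizons, multiplicative
# observation noise and quantitation-limit censoring. The most stressful
# 60 degC arm of real programs is deliberately absent from the default:
# the kinetic model is built from 30-50 degC data only.

#' Factorial stability-study design
#'
#' @param peg_saxa_ratios PEG:SAXA weight ratios (default 0.8, 1.0, 1.2,
#'   1.4).
#' @param temps_C Storage temperatures, degC (default 30, 40, 50).
#' @param aw Nominal water activities (default 0.10, 0.30, 0.50).
#' @param times Sampling times, days; must include 0 and hold at least four
#'   points per condition (default 0, 7, 14, 30, 60, 108, 180).
#' @param sigma Multiplicative Gaussian noise standard deviation (relative;
#'   default 0.05, the approximate relative error of a UHPLC assay).
#' @param loq_ppm Quantitation limit applied to every measured species, ppm
#'   w/w of film coat (default 5).
#' @param saxa_massfrac Saxagliptin film-coat loading, kg/kg (default 0.25);
#'   held constant across compositions.
#' @param ph_mode Micro-environmental pH handling for the generated
#'   conditions (default `"dynamic"`).
#' @param include_ph Also emit the derived pH series as response rows
#'   (species `"pH"`, uncensored, noise-free)? Default `TRUE`.
#' @param seed RNG seed making the generated study reproducible.
#' @return Object of class `study_design`.
#' @export
study_design <- function(peg_saxa_ratios = c(0.8, 1.0, 1.2, 1.4),
                         temps_C = c(30, 40, 50),
                         aw = c(0.10, 0.30, 0.50),
                         times = c(0, 7, 14, 30, 60, 108, 180),
                         sigma = 0.05, loq_ppm = 5,
                         saxa_massfrac = 0.25,
                         ph_mode = c("dynamic", "measured"),
                         include_ph = TRUE, seed = 1L) {
  ph_mode <- match.arg(ph_mode)
  if (length(peg_saxa_ratios) < 1L || length(temps_C) < 1L ||
      length(aw) < 1L) {
    stop("all design factors must be non-empty", call. = FALSE)
  }
  if (length(times) < 4L) {
    stop("at least four time points per condition are required",
         call. = FALSE)
  }
  if (times[1L] != 0 || any(diff(times) <= 0)) {
    stop("times must start at 0 and be strictly increasing", call. = FALSE)
  }
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(peg_saxa_ratios = peg_saxa_ratios, temps_C = temps_C,
                 aw = aw, times = times, sigma = sigma, loq_ppm = loq_ppm,
                 saxa_massfrac = saxa_massfrac, ph_mode = ph_mode,
                 include_ph = isTRUE(include_ph), seed = as.integer(seed)),
            class = "study_design")
}

#' Film-coat composition from the PEG:SAXA weight ratio
#'
#' Converts the design's weight ratios, on a per-kg-film-coat basis, into
#' molar totals. The drug loading is fixed across compositions (the same
#' amount of saxagliptin is layered in every formulation); PEG mass is
#' `ratio * saxa_massfrac` and hypromellose makes up the remainder of the
#' coat, which fixes the matched PEG:HPMC weight ratio.
#'
#' @param peg_saxa_ratio PEG:SAXA weight ratio (> 0).
#' @param saxa_massfrac Saxagliptin loading, kg per kg film coat.
#' @return List with `init` (an [initial_composition()], mol/kg),
#'   `peg_hpmc_ratio`, and the weight fractions `w_peg`, `w_saxa`,
#'   `w_hpmc`.
#' @export
#' @examples
#' make_initial_composition(1.4)
make_initial_composition <- function(peg_saxa_ratio, saxa_massfrac = 0.25) {
  if (peg_saxa_ratio <= 0) stop("ratio must be > 0", call. = FALSE)
  w_saxa <- saxa_massfrac
  w_peg <- peg_saxa_ratio * w_saxa
  w_hpmc <- 1 - w_saxa - w_peg
  if (w_hpmc <= 0) {
    stop("composition exceeds the film-coat mass basis", call. = FALSE)
  }
  list(init = initial_composition(
         convert_units(w_peg, "massfrac", "mol_kg", species = "PEG"),
         convert_units(w_saxa, "massfrac", "mol_kg", species = "SAXA")),
       peg_hpmc_ratio = w_peg / w_hpmc,
       w_peg = w_peg, w_saxa = w_saxa, w_hpmc = w_hpmc)
}

#' Generate a synthetic stability study
#'
#' Simulates every condition of the design under `params`, samples the
#' trajectories at the design time points, applies multiplicative Gaussian
#' noise `value * (1 + sigma * z)` truncated at 0, and censors values below
#' the species LOQ (stored as the LOQ with the `below_loq` flag set).
#' Reactive PEG itself is not observable by the assay, so observations
#' cover the eight measured species (GA, A, F, FA, SAXA, SCA, ESCA, SFA)
#' plus, optionally, the derived pH. Deterministic given the design seed.
#'
#' @param design A [study_design()].
#' @param params True [kinetic_parameters()] used for generation (recorded
#'   in the result's `truth` attribute).
#' @param tol,dt_init Integrator settings.
#' @return List of [stability_dataset()], one per condition, with
#'   attributes `truth` (the generating parameters) and `design`.
#' @export
#' @examples
#' d <- study_design(peg_saxa_ratios = c(0.8, 1.4), temps_C = 40,
#'                   aw = 0.10, times = c(0, 30, 90, 180), sigma = 0)
#' generate_study(d)
generate_study <- function(design, params = default_parameters(),
                           tol = 1e-5, dt_init = 1) {
  stopifnot(inherits(design, "study_design"),
            inherits(params, "kinetic_parameters"))
  set.seed(design$seed)
  measured <- setdiff(SPECIES, "PEG")
  loq <- vapply(measured, function(s) {
    convert_units(design$loq_ppm, "ppm_ww", "mol_kg", species = s)
  }, numeric(1))
  out <- list()
  for (ratio in design$peg_saxa_ratios) {
    comp <- make_initial_composition(ratio, design$saxa_massfrac)
    for (temp in design$temps_C) {
      for (a in design$aw) {
        env <- stability_condition(temp, a, ratio, comp$peg_hpmc_ratio,
                                   ph_mode = design$ph_mode,
                                   ph_measured = NULL)
        traj <- simulate_kinetics(comp$init, params, env, design$times,
                                  tol = tol, dt_init = dt_init)
        nt <- length(design$times)
        vals <- as.vector(traj$states[, measured])
        z <- stats::rnorm(length(vals))
        noisy <- pmax(0, vals * (1 + design$sigma * z))
        sp <- rep(measured, each = nt)
        below <- noisy < loq[sp]
        noisy[below] <- loq[sp][below]
        obs <- data.frame(time_days = rep(design$times, length(measured)),
                          species = sp, value = noisy,
                          below_loq = as.integer(below))
        if (design$include_ph) {
          obs <- rbind(obs, data.frame(time_days = design$times,
                                       species = "pH", value = traj$pH,
                                       below_loq = 0L))
        }
        id <- sprintf("R%.1f_T%g_RH%02d", ratio, temp, round(100 * a))
        out[[id]] <- stability_dataset(id, env, comp$init, obs, loq = loq)
      }
    }
  }
  attr(out, "truth") <- params
  attr(out, "design") <- design
  out
}
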