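# Delimited-table and parameter-file plumbing. One CSV dialect throughout:
# comma separator, '.' decimal, UTF-8, mandatory header row.

#' Write a stability study as observation + condition tables
#'
#' Observations: `condition_id, time_days, species, value, unit,
#' below_loq`; conditions: `condition_id, temp_C, aw, peg_saxa_ratio,
#' peg_hpmc_ratio, ph_measured` (empty in dynamic pH mode). Values are
#' written in mol/kg (`unit = "molkg"`); pH rows carry `unit = "pH"`.
#'
#' @param datasets List of [stability_dataset()].
#' @param obs_path,cond_path Output CSV paths.
#' @return `obs_path`, invisibly.
#' @export
write_study_csv <- function(datasets, obs_path, cond_path) {
  obs <- do.call(rbind, lapply(datasets, function(d) {
    o <- d$observations
    data.frame(condition_id = d$condition_id, time_days = o$time_days,
               species = o$species, value = o$value,
               unit = ifelse(o$species == "pH", "pH", "molkg"),
               below_loq = o$below_loq)
  }))
  cond <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(condition_id = d$condition_id, temp_C = d$env$temp_C,
               aw = d$env$aw, peg_saxa_ratio = d$env$peg_saxa_ratio,
               peg_hpmc_ratio = d$env$peg_hpmc_ratio,
               ph_measured = if (d$env$ph_mode == "measured")
                 d$env$ph_measured else NA_real_)
  }))
  utils::write.csv(obs, obs_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(cond, cond_path, row.names = FALSE, quote = FALSE)
  invisible(obs_path)
}

#' Read a stability study from observation + condition tables
#'
#' Inverse of [write_study_csv()]. Initial compositions are reconstructed
#' from the PEG:SAXA weight ratio at a fixed drug loading (see
#' [make_initial_composition()]); concentration rows with `unit = "ppm_ww"`
#' are converted to mol/kg using the species molar mass. Per-species LOQs
#' are recovered from the censored rows (which store the LOQ as value).
#'
#' @param obs_path,cond_path Input CSV paths.
#' @param saxa_massfrac Saxagliptin film-coat loading, kg/kg (default 0.25).
#' @return List of [stability_dataset()].
#' @export
read_study_csv <- function(obs_path, cond_path, saxa_massfrac = 0.25) {
  obs <- utils::read.csv(obs_path, stringsAsFactors = FALSE)
  cond <- utils::read.csv(cond_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(cond)), function(i) {
    ci <- cond[i, ]
    o <- obs[obs$condition_id == ci$condition_id, , drop = FALSE]
    if (nrow(o) == 0L) {
      stop("no observations for condition ", ci$condition_id, call. = FALSE)
    }
    ppm <- o$unit == "ppm_ww"
    if (any(ppm)) {
      o$value[ppm] <- mapply(function(v, s) {
        convert_units(v, "ppm_ww", "mol_kg", species = s)
      }, o$value[ppm], o$species[ppm])
    }
    measured <- "ph_measured" %in% names(ci) && !is.na(ci$ph_measured)
    env <- stability_condition(
      ci$temp_C, ci$aw, ci$peg_saxa_ratio, ci$peg_hpmc_ratio,
      ph_mode = if (measured) "measured" else "dynamic",
      ph_measured = if (measured) ci$ph_measured else NULL)
    comp <- make_initial_composition(ci$peg_saxa_ratio,
                                     saxa_massfrac = saxa_massfrac)
    cens <- o[o$below_loq == 1, , drop = FALSE]
    loq <- if (nrow(cens)) tapply(cens$value, cens$species, max) else numeric()
    stability_dataset(
      ci$condition_id, env, comp$init,
      data.frame(time_days = o$time_days, species = o$species,
                 value = o$value, below_loq = o$below_loq),
      loq = c(loq))
  })
}

#' Write kinetic parameters as a JSON parameter file
#'
#' The file round-trips through [read_params_json()] and is accepted
#' wherever a [kinetic_parameters()] object is, including the command-line
#' `simulate` subcommand.
#'
#' @param params A [kinetic_parameters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path) {
  x <- unclass(params)
  x$k_ref <- as.list(x$k_ref)
  x$Ea <- as.list(x$Ea)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read kinetic parameters from a JSON parameter file
#'
#' @param path Path written by [write_params_json()].
#' @return A [kinetic_parameters()].
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  kinetic_parameters(
    k_ref = unlist(x$k_ref), Ea = unlist(x$Ea), T_ref_C = x$T_ref_C,
    k8 = x$k8, kHp = x$kHp, Kw = x$Kw, ph_slope = x$ph_slope,
    ph_intercept = x$ph_intercept, ph_floor = x$ph_floor,
    x_saxa = x$x_saxa, consume_fa = x$consume_fa,
    phase_corrected = x$phase_corrected)
}

#' Write a fit report
#'
#' Plain-text summary (`<stem>.txt`) plus a machine-readable parameter file
#' (`<stem>_params.json`) usable as [simulate_kinetics()] input.
#'
#' @param fit A `kin_fit` from [fit_kinetics()] or [fit_sequence()].
#' @param stem Output path stem (without extension).
#' @return The text report path, invisibly.
#' @export
write_fit_report <- function(fit, stem) {
  txt <- paste0(stem, ".txt")
  con <- file(txt, "w")
  on.exit(close(con))
  writeLines(c(
    "saxakin fit report",
    sprintf("free parameters : %s", paste(fit$free, collapse = ", ")),
    sprintf("observations    : %d", fit$n_obs),
    sprintf("weighted SSE    : %.10g", fit$residual_sum),
    sprintf("converged       : %s", fit$converged),
    sprintf("iterations      : %d", fit$iterations),
    sprintf("message         : %s", trimws(fit$message)),
    "",
    "fitted values:",
    paste(sprintf("  %-5s = %.10g", fit$free,
                  get_free_params(fit$params, fit$free)),
          collapse = "\n")
  ), con)
  write_params_json(fit$params, paste0(stem, "_params.json"))
  invisible(txt)
}
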