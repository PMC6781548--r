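#' Arrhenius rate constant
#'
#' `k = A * exp(-Ea / (R * T))` with R = 8.314462618 J/(mol K).
#'
#' @param A Pre-exponential factor (same unit as the returned constant,
#'   per day throughout this package); >= 0.
#' @param Ea Activation energy, kJ/mol.
#' @param T_K Absolute temperature, K (> 0).
#' @return Rate constant in the unit of `A`.
#' @export
#' @examples
#' arrhenius(5, 0, 313.15)        # zero barrier: k = A
#' arrhenius(1, 88.54, 313.15)
arrhenius <- function(A, Ea, T_K) {
  if (any(A < 0)) stop("A must be >= 0", call. = FALSE)
  if (any(T_K <= 0)) stop("temperature must be positive (K)", call. = FALSE)
  A * exp(-Ea * 1000 / (saxakin_constants()$R_J_per_mol_K * T_K))
}

#' Micro-environmental pH from the formic-acid mass fraction
#'
#' Linear closure `pH = intercept + slope * w_FA`, with the formic-acid
#' concentration expressed as mass fraction (kg FA per kg film coat). The
#' default coefficients (slope -570.45, intercept 5.6703) make the film-coat
#' pH fall by ~0.1-0.2 units for a few hundred ppm of formic acid, matching
#' the measured range. Results extrapolating below `floor` are clipped with
#' a warning.
#'
#' @param w_FA Formic-acid mass fraction, kg/kg, >= 0. Vectorized.
#' @param slope,intercept Closure coefficients.
#' @param floor Lower clip for the extrapolation (default 1.0).
#' @return pH (vector).
#' @export
#' @examples
#' ph_from_fa(0)        # 5.6703
#' ph_from_fa(3.5e-4)
ph_from_fa <- function(w_FA,
                       slope = saxakin_constants()$ph_slope,
                       intercept = saxakin_constants()$ph_intercept,
                       floor = 1.0) {
  if (any(w_FA < 0)) stop("w_FA must be >= 0", call. = FALSE)
  pH <- intercept + slope * w_FA
  if (any(pH < floor)) {
    warning("pH closure extrapolated below floor ", floor, "; clipped",
            call. = FALSE)
    pH <- pmax(pH, floor)
  }
  pH
}

#' Hydrogen and hydroxide ion concentrations from pH
#'
#' @param pH pH value(s).
#' @param Kw Water ionization constant, mol^2 L^-2 (> 0).
#' @return Named list with `cH` and `cOH`, mol/L.
#' @export
#' @examples
#' hydrogen_hydroxide(7)  # neutral water: both 1e-7
hydrogen_hydroxide <- function(pH, Kw = saxakin_constants()$Kw_default) {
  if (Kw <= 0) stop("Kw must be > 0", call. = FALSE)
  cH <- 10^(-pH)
  list(cH = cH, cOH = Kw / cH)
}

#' Out-of-phase PEG fraction vs PEG-to-polymer weight ratio
#'
#' Piecewise-linear interpolation through the melt-behaviour anchor points
#' for PEG dispersed in a higher-melting film polymer: at a 10% w/w ratio no
#' PEG is out of phase, at 20% about 5%, and at 30% already about 22%.
#' Below 10% the fraction is 0; above 30% the last segment is extrapolated
#' linearly; the result is clipped to `[0, 1]`. Only out-of-phase
#' (phase-incompatible) PEG retains the molecular mobility to degrade.
#'
#' @param ratio PEG w/w ratio relative to the film polymer, >= 0.
#'   Vectorized.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' out_of_phase_fraction(c(0.10, 0.20, 0.25, 0.30))
out_of_phase_fraction <- function(ratio) {
  if (any(ratio < 0)) stop("ratio must be >= 0", call. = FALSE)
  cst <- saxakin_constants()
  x <- cst$phase_anchor_ratio
  y <- cst$phase_anchor_fraction
  n <- length(x)
  slope_last <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  f <- ifelse(ratio <= x[1], 0,
         ifelse(ratio >= x[n],
                y[n] + slope_last * (ratio - x[n]),
                approx(x, y, xout = pmin(pmax(ratio, x[1]), x[n]))$y))
  pmin(pmax(f, 0), 1)
}

#' Reactive PEG fraction under a storage condition
#'
#' Surface water provides the reaction medium for PEG oxidation, so the
#' reactive fraction is proportional to water activity,
#' `x_PEG = kHp * aw` (the Henry adsorption constant and water's
#' stoichiometric coefficient folded into `kHp`). With the
#' phase-compatibility correction enabled, the humidity term is multiplied
#' by the out-of-phase fraction at the condition's PEG-to-polymer weight
#' ratio (PEG over PEG + HPMC): phase-compatible PEG is immobilized and does
#' not degrade. The result is clipped to `[0, 1]`.
#'
#' @param env A [stability_condition()].
#' @param kHp Humidity proportionality (dimensionless per unit water
#'   activity).
#' @param phase_corrected Apply the out-of-phase factor? Default `TRUE`.
#' @return `x_PEG` in `[0, 1]`.
#' @export
reactive_peg_fraction <- function(env, kHp, phase_corrected = TRUE) {
  x <- kHp * env$aw
  if (isTRUE(phase_corrected)) {
    peg_polymer <- env$peg_hpmc_ratio / (1 + env$peg_hpmc_ratio)
    x <- x * out_of_phase_fraction(peg_polymer)
  }
  min(max(x, 0), 1)
}

#' Mixing enthalpy of a two-component blend
#'
#' Mass-weighted sum `dH_mix = x1 * dH1 + x2 * dH2`, the ideal-mixing DSC
#' closure used to quantify phase-compatible PEG in an HPMC matrix (HPMC
#' has no melting event in the relevant range, so the blend's melting
#' enthalpy tracks the free PEG weight fraction).
#'
#' @param x1,x2 Weight fractions, >= 0, summing to 1 within 1e-9.
#' @param dH1,dH2 Component melting enthalpies, J/g.
#' @return Mixture enthalpy, J/g.
#' @export
#' @examples
#' mixing_enthalpy(0.3, 190, 0.7, 0)  # 57
mixing_enthalpy <- function(x1, dH1, x2, dH2) {
  if (x1 < 0 || x2 < 0) stop("weight fractions must be >= 0", call. = FALSE)
  if (abs(x1 + x2 - 1) > 1e-9) {
    stop("weight fractions must sum to 1", call. = FALSE)
  }
  x1 * dH1 + x2 * dH2
}

# pH prevailing for a state under a condition: measured value or dynamic
# formic-acid closure (concentration converted mol/kg -> mass fraction).
microenvironment_ph <- function(state, params, env) {
  if (env$ph_mode == "measured") {
    return(env$ph_measured)
  }
  w_FA <- unclass(state)[["FA"]] * saxakin_constants()$M_FA / 1000
  pH <- params$ph_intercept + params$ph_slope * w_FA
  max(pH, params$ph_floor)
}

#' Reaction rates of the degradation network
#'
#' Mass-action rate laws with surplus oxygen folded into the apparent
#' constants: `r1 = k1' c_PEG`, `r2 = k2' c_PEG`, `r3 = k3' c_PEG`,
#' `r4 = k4' c_F`, `r5 = k5' c_OH c_SAXA`, `r6 = k6' c_OH c_SCA`, and the
#' net formylation rate `r7 = k7' c_H c_SAXA c_FA - k8' c_SFA` (irreversible
#' when `k8 = 0`). The ion concentrations come from the condition's measured
#' pH or, in dynamic mode, from the formic-acid pH closure evaluated at the
#' current state.
#'
#' @param state A [species_state()].
#' @param params A [kinetic_parameters()].
#' @param env A [stability_condition()].
#' @return Named numeric `r1..r7`, mol/(kg day), with attributes `pH`,
#'   `cH`, `cOH`.
#' @export
compute_rates <- function(state, params, env) {
  y <- unclass(state)
  k <- apparent_rate_constants(params, env$T_K)
  pH <- microenvironment_ph(state, params, env)
  ions <- hydrogen_hydroxide(pH, params$Kw)
  r <- c(
    r1 = k[["k1"]] * y[["PEG"]],
    r2 = k[["k2"]] * y[["PEG"]],
    r3 = k[["k3"]] * y[["PEG"]],
    r4 = k[["k4"]] * y[["F"]],
    r5 = k[["k5"]] * ions$cOH * y[["SAXA"]],
    r6 = k[["k6"]] * ions$cOH * y[["SCA"]],
    r7 = k[["k7"]] * ions$cH * y[["SAXA"]] * y[["FA"]] - params$k8 * y[["SFA"]]
  )
  attr(r, "pH") <- pH
  attr(r, "cH") <- ions$cH
  attr(r, "cOH") <- ions$cOH
  r
}

#' Time derivative of the species state
#'
#' Stoichiometric balance of the network: each PEG oxidation (r1-r3)
#' consumes one reactive PEG unit, formaldehyde oxidizes on to formic acid
#' (r4), saxagliptin cyclizes serially to the amidine and its epimer
#' (r5, r6) and is formylated in parallel (r7). Formic acid forms
#' exclusively through formaldehyde oxidation and, with `consume_fa` (the
#' default), is debited stoichiometrically by net formylation, which keeps
#' the PEG-family molar total exactly conserved.
#'
#' @inheritParams compute_rates
#' @return Named numeric derivative vector over [SPECIES], mol/(kg day).
#' @export
ode_rhs <- function(state, params, env) {
  r <- compute_rates(state, params, env)
  cf <- as.numeric(params$consume_fa)
  c(PEG = -(r[["r1"]] + r[["r2"]] + r[["r3"]]),
    GA = r[["r1"]],
    A = r[["r2"]],
    F = r[["r3"]] - r[["r4"]],
    FA = r[["r4"]] - cf * r[["r7"]],
    SAXA = -r[["r5"]] - r[["r7"]],
    SCA = r[["r5"]] - r[["r6"]],
    ESCA = r[["r6"]],
    SFA = r[["r7"]])
}
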