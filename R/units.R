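#' Convert between the units used at the package boundaries
#'
#' Supported pairs: `kcal/mol` <-> `kJ/mol` (thermochemical calorie, factor
#' 4.184), `ppm_ww` <-> `massfrac` (parts per million w/w of film coat vs
#' kg/kg), and `massfrac` <-> `mol_kg` (requires `species` for the molar
#' mass). `ppm_ww` <-> `mol_kg` is accepted as the composition of the two
#' mass-based steps. Values are converted exactly; use [display_round()]
#' only when printing.
#'
#' @param value Numeric vector to convert.
#' @param from,to Unit names: `"kcal/mol"`, `"kJ/mol"`, `"ppm_ww"`,
#'   `"massfrac"`, `"mol_kg"`.
#' @param species Species name (see [SPECIES]); required for conversions
#'   involving `mol_kg`.
#' @return Converted numeric vector.
#' @export
#' @examples
#' convert_units(39.28, "kcal/mol", "kJ/mol")   # 164.34752
#' convert_units(350, "ppm_ww", "massfrac")     # 3.5e-4
#' convert_units(3.5e-4, "massfrac", "mol_kg", species = "FA")
convert_units <- function(value, from, to, species = NULL) {
  units <- c("kcal/mol", "kJ/mol", "ppm_ww", "massfrac", "mol_kg")
  from <- match.arg(from, units)
  to <- match.arg(to, units)
  if (from == to) return(value)
  cst <- saxakin_constants()
  energy <- c("kcal/mol", "kJ/mol")
  mass <- c("ppm_ww", "massfrac", "mol_kg")
  if (from %in% energy && to %in% energy) {
    return(if (from == "kcal/mol") value * cst$kcal_to_kJ
           else value / cst$kcal_to_kJ)
  }
  if (from %in% mass && to %in% mass) {
    # route through mass fraction (kg/kg)
    w <- switch(from,
      ppm_ww = value * 1e-6,
      massfrac = value,
      mol_kg = {
        if (is.null(species)) {
          stop("species required for mol_kg conversions", call. = FALSE)
        }
        value * molar_mass(species) / 1000
      })
    return(switch(to,
      ppm_ww = w * 1e6,
      massfrac = w,
      mol_kg = {
        if (is.null(species)) {
          stop("species required for mol_kg conversions", call. = FALSE)
        }
        w * 1000 / molar_mass(species)
      }))
  }
  stop("unsupported unit pair: ", from, " -> ", to, call. = FALSE)
}

#' Round for display
#'
#' Round-half-even at a fixed number of decimals, for printing converted
#' values. Internal computations are never rounded.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' display_round(convert_units(39.28, "kcal/mol", "kJ/mol")) # 164.35
display_round <- function(x, digits = 2) {
  round(x, digits)
}
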