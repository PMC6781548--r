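#' @keywords internal
#' @importFrom stats approx cor lm.fit rnorm sd setNames
#' @importFrom utils head packageVersion read.csv write.csv
"_PACKAGE"

# Package-wide cache (constants parsed once per session).
.saxakin <- new.env(parent = emptyenv())

#' Tracked chemical species, in canonical order
#'
#' PEG is the pool of reactive polyethylene-glycol monomer units; GA, A, F,
#' FA are its oxidation products (glycolic acid, acetaldehyde, formaldehyde,
#' formic acid); SAXA is saxagliptin and SCA, ESCA, SFA its cyclic amidine,
#' epimerized cyclic amidine and formyl amide degradation products. All
#' internal concentrations are molar equivalents per kg of film coat.
#'
#' @format Character vector of the nine species names.
#' @export
SPECIES <- c("PEG", "GA", "A", "F", "FA", "SAXA", "SCA", "ESCA", "SFA")

parse_constants_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) {
      stop("malformed constants line: ", ln, call. = FALSE)
    }
    key <- trimws(kv[1L])
    val <- as.numeric(trimws(strsplit(kv[2L], ",", fixed = TRUE)[[1L]]))
    if (anyNA(val)) stop("non-numeric constant for key ", key, call. = FALSE)
    out[[key]] <- val
  }
  out
}

#' Physical constants and species molar masses
#'
#' Reads the plain-text constants resource shipped with the package (gas
#' constant, calorie conversion factor, default water ionization constant,
#' species molar masses, phase-compatibility lookup anchors, pH-closure
#' coefficients) and caches it for the session.
#'
#' @return Named list of numeric constants (scalars or short vectors).
#' @export
#' @examples
#' saxakin_constants()$M_FA
saxakin_constants <- function() {
  if (is.null(.saxakin$constants)) {
    path <- system.file("extdata", "constants.txt", package = "saxakin")
    if (!nzchar(path)) stop("constants resource not found", call. = FALSE)
    .saxakin$constants <- parse_constants_file(path)
  }
  .saxakin$constants
}

#' Molar mass of a tracked species
#'
#' @param species One of [SPECIES].
#' @return Molar mass in g/mol (PEG per ethylene-oxide repeat unit).
#' @export
#' @examples
#' molar_mass("FA") # 46.025
molar_mass <- function(species) {
  species <- match.arg(species, SPECIES)
  saxakin_constants()[[paste0("M_", species)]]
}
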