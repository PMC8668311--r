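#' @keywords internal
"_PACKAGE"

## Gas constant, J mol^-1 K^-1 (fixed; no per-call override)
R_GAS <- 8.314

## Minutes per year used for shelf-life reporting (365 * 24 * 60)
MIN_PER_YEAR <- 525600

#' Convert Celsius to Kelvin
#' @param x temperature in degrees Celsius
#' @return temperature in kelvin
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' Convert Kelvin to Celsius
#' @param x temperature in kelvin
#' @return temperature in degrees Celsius
#' @export
kelvin_to_celsius <- function(x) x - 273.15

## IUPAC standard atomic weights (conventional values, g mol^-1)
.ATOMIC_WEIGHTS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, P = 30.974, S = 32.06, Cl = 35.45,
  K = 39.098, Ca = 40.078, Mn = 54.938, Fe = 55.845, Cu = 63.546,
  Zn = 65.38, Br = 79.904, I = 126.904
)

#' Molar mass from a molecular formula
#'
#' Parses a simple Hill-style formula such as `"C48H44Cl5MnN8"` (element
#' symbols followed by optional integer counts, no parentheses) and returns
#' the molar mass in g/mol. Used to derive the stoichiometric mass-loss
#' fractions of multi-step synthetic TG fixtures from first principles
#' instead of hard-coding them.
#'
#' @param formula character scalar, e.g. `"H2O"`, `"C2H5Cl"`.
#' @return molar mass in g/mol.
#' @examples
#' molar_mass("H2O")     # 18.015
#' molar_mass("C2H5Cl")  # ethyl chloride, 64.51
#' @export
molar_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  total <- 0
  for (tok in tokens) {
    sym <- sub("[0-9]+$", "", tok)
    cnt <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(cnt)) as.numeric(cnt) else 1
    w <- unname(.ATOMIC_WEIGHTS[sym])
    if (is.na(w)) stop("unknown element symbol '", sym, "' in formula ", formula)
    total <- total + n * w
  }
  total
}
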