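#' Physical constants
#'
#' SI-exact constants used throughout the package. `kBoltzmann` is the
#' Boltzmann constant in J/K (2019 SI definition, exact); `nAvogadro` is the
#' Avogadro constant in 1/mol (exact); `eCharge` is the elementary charge in
#' coulomb (exact).
#'
#' @examples
#' kBoltzmann * 300  # thermal energy at 300 K, joule
#' @export
kBoltzmann <- 1.380649e-23

#' @rdname kBoltzmann
#' @export
nAvogadro <- 6.02214076e23

#' @rdname kBoltzmann
#' @export
eCharge <- 1.602176634e-19

## Unit registry.  Each entry: factor to SI and dimension exponents over the
## base (m, kg, s, K, mol is always folded out: "per mole" quantities are
## converted to per molecule).  Internally everything is SI; conventional
## units (nm, ps, kJ/mol, mJ/m^2, nm^-3, ...) appear only at the boundary.
.unitTable <- list(
  "1"        = list(factor = 1,                 dim = c(m = 0, kg = 0, s = 0, K = 0)),
  "K"        = list(factor = 1,                 dim = c(m = 0, kg = 0, s = 0, K = 1)),
  "m"        = list(factor = 1,                 dim = c(m = 1, kg = 0, s = 0, K = 0)),
  "nm"       = list(factor = 1e-9,              dim = c(m = 1, kg = 0, s = 0, K = 0)),
  "s"        = list(factor = 1,                 dim = c(m = 0, kg = 0, s = 1, K = 0)),
  "ps"       = list(factor = 1e-12,             dim = c(m = 0, kg = 0, s = 1, K = 0)),
  "ns"       = list(factor = 1e-9,              dim = c(m = 0, kg = 0, s = 1, K = 0)),
  "J"        = list(factor = 1,                 dim = c(m = 2, kg = 1, s = -2, K = 0)),
  "kJ/mol"   = list(factor = 1e3 / nAvogadro,   dim = c(m = 2, kg = 1, s = -2, K = 0)),
  "J/mol"    = list(factor = 1 / nAvogadro,     dim = c(m = 2, kg = 1, s = -2, K = 0)),
  "J/K"      = list(factor = 1,                 dim = c(m = 2, kg = 1, s = -2, K = -1)),
  "kJ/mol/K" = list(factor = 1e3 / nAvogadro,   dim = c(m = 2, kg = 1, s = -2, K = -1)),
  "J/mol/K"  = list(factor = 1 / nAvogadro,     dim = c(m = 2, kg = 1, s = -2, K = -1)),
  "J/m^2"    = list(factor = 1,                 dim = c(m = 0, kg = 1, s = -2, K = 0)),
  "mJ/m^2"   = list(factor = 1e-3,              dim = c(m = 0, kg = 1, s = -2, K = 0)),
  "J/m^3"    = list(factor = 1,                 dim = c(m = -1, kg = 1, s = -2, K = 0)),
  "m^2"      = list(factor = 1,                 dim = c(m = 2, kg = 0, s = 0, K = 0)),
  "nm^2"     = list(factor = 1e-18,             dim = c(m = 2, kg = 0, s = 0, K = 0)),
  "m^3"      = list(factor = 1,                 dim = c(m = 3, kg = 0, s = 0, K = 0)),
  "nm^3"     = list(factor = 1e-27,             dim = c(m = 3, kg = 0, s = 0, K = 0)),
  "m^-3"     = list(factor = 1,                 dim = c(m = -3, kg = 0, s = 0, K = 0)),
  "nm^-3"    = list(factor = 1e27,              dim = c(m = -3, kg = 0, s = 0, K = 0)),
  "m^-1"     = list(factor = 1,                 dim = c(m = -1, kg = 0, s = 0, K = 0)),
  "nm^-1"    = list(factor = 1e9,               dim = c(m = -1, kg = 0, s = 0, K = 0)),
  "m^2/s"    = list(factor = 1,                 dim = c(m = 2, kg = 0, s = -1, K = 0)),
  "nm^2/ps"  = list(factor = 1e-6,              dim = c(m = 2, kg = 0, s = -1, K = 0)),
  "m/s"      = list(factor = 1,                 dim = c(m = 1, kg = 0, s = -1, K = 0)),
  "nm/ps"    = list(factor = 1e3,               dim = c(m = 1, kg = 0, s = -1, K = 0)),
  "m^-3*s^-1"  = list(factor = 1,               dim = c(m = -3, kg = 0, s = -1, K = 0)),
  "nm^-3*s^-1" = list(factor = 1e27,            dim = c(m = -3, kg = 0, s = -1, K = 0))
)

.lookupUnit <- function(unit) {
  entry <- .unitTable[[unit]]
  if (is.null(entry))
    stop("unrecognized unit string: '", unit, "'", call. = FALSE)
  entry
}

#' Convert between conventional units and internal SI
#'
#' `toSI()` converts values expressed in a recognized conventional unit to
#' the package's internal SI representation; `fromSI()` is its inverse.
#' "Per mole" energies are converted to per molecule (division by the
#' Avogadro constant), so e.g. `toSI(10, "kJ/mol")` is joule per molecule.
#' The two functions are exactly involutive: `fromSI(toSI(x, u), u) == x`
#' up to floating-point roundoff.
#'
#' @param x numeric vector.
#' @param unit unit string, e.g. `"nm"`, `"ps"`, `"kJ/mol"`, `"mJ/m^2"`,
#'   `"nm^-3"`, `"nm^2/ps"`.
#' @return numeric vector of the same length.
#' @examples
#' toSI(10, "kJ/mol")     # J per molecule
#' fromSI(2.53e-3, "mJ/m^2")
#' @export
toSI <- function(x, unit) x * .lookupUnit(unit)$factor

#' @rdname toSI
#' @export
fromSI <- function(x, unit) x / .lookupUnit(unit)$factor

#' Dimension exponents of a recognized unit
#'
#' Returns the exponents of a unit over the SI base dimensions
#' (m, kg, s, K).  Used by the rate assembly to audit that composed
#' quantities reduce to the expected dimensions (a nucleation rate must be
#' inverse volume times inverse time, a growth rate length per time).
#'
#' @param unit unit string.
#' @return named integer vector with elements `m`, `kg`, `s`, `K`.
#' @examples
#' unitDimensions("m^2/s")
#' @export
unitDimensions <- function(unit) .lookupUnit(unit)$dim

## dimension arithmetic for the audit: dims are named numeric vectors
.dimProduct <- function(...) Reduce(`+`, list(...))
.dimPower <- function(d, p) d * p
.dimEqual <- function(a, b, tol = 1e-9) all(abs(a - b) < tol)
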