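#' @import methods
NULL

## ---------------------------------------------------------------------------
## Frame: positions of molecular centers in a periodic box at one time point
## ---------------------------------------------------------------------------

#' Frame: molecular centers in a periodic box
#'
#' A `Frame` holds the positions of molecular geometric centers in an
#' orthorhombic periodic box at one time point.  Coordinates are stored
#' wrapped into `[0, L)` per axis (half-open box convention, minimum image
#' everywhere downstream); an optional `unwrapped` matrix retains the
#' continuous trajectory coordinates needed for mean-square displacements.
#'
#' @slot time time point, ps.
#' @slot box three strictly positive edge lengths `(Lx, Ly, Lz)`, nm.
#' @slot coords n x 3 matrix of wrapped coordinates, nm.
#' @slot unwrapped n x 3 matrix of unwrapped coordinates, nm (0-row matrix
#'   when not available).
#' @slot labels per-molecule phase label, one of `"solid"`, `"liquid"`,
#'   `"unknown"` (length 0 when no ground truth is attached).
#'
#' @aliases Frame-class
#' @export Frame
#' @exportClass Frame
Frame <- setClass("Frame",
  representation(
    time = "numeric",
    box = "numeric",
    coords = "matrix",
    unwrapped = "matrix",
    labels = "character"
  ),
  prototype(
    time = 0,
    box = c(1, 1, 1),
    coords = matrix(numeric(0), ncol = 3),
    unwrapped = matrix(numeric(0), ncol = 3),
    labels = character(0)
  )
)

setValidity("Frame", function(object) {
  msg <- character(0)
  if (length(object@box) != 3L || any(!is.finite(object@box)) ||
      any(object@box <= 0))
    msg <- c(msg, "box must be three strictly positive edge lengths")
  if (ncol(object@coords) != 3L)
    msg <- c(msg, "coords must have three columns")
  n <- nrow(object@coords)
  if (n > 0) {
    for (ax in 1:3)
      if (any(object@coords[, ax] < 0 | object@coords[, ax] >= object@box[ax]))
        msg <- c(msg, sprintf("coordinates on axis %d not wrapped into [0, L)", ax))
  }
  if (nrow(object@unwrapped) > 0 && nrow(object@unwrapped) != n)
    msg <- c(msg, "unwrapped must have the same number of rows as coords")
  if (length(object@labels) > 0) {
    if (length(object@labels) != n)
      msg <- c(msg, "labels must match the number of molecules")
    if (!all(object@labels %in% c("solid", "liquid", "unknown")))
      msg <- c(msg, "labels must be 'solid', 'liquid' or 'unknown'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Frame, wrapping coordinates into the box
#'
#' @param coords n x 3 matrix of coordinates, nm; wrapped into `[0, L)`.
#' @param box three positive edge lengths, nm.
#' @param time time point, ps.
#' @param unwrapped optional n x 3 matrix of unwrapped coordinates, nm.
#' @param labels optional per-molecule phase labels.
#' @return a [Frame-class] object.
#' @examples
#' fr <- makeFrame(matrix(c(-0.2, 0, 0), ncol = 3), box = c(10, 10, 10))
#' positions(fr)  # wrapped to (9.8, 0, 0)
#' @export
makeFrame <- function(coords, box, time = 0,
                      unwrapped = NULL, labels = character(0)) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  if (length(box) != 3L || any(box <= 0)) stop("box must be 3 positive edges")
  wrapped <- wrapCoords(coords, box)
  if (is.null(unwrapped)) unwrapped <- matrix(numeric(0), ncol = 3)
  new("Frame", time = as.numeric(time), box = as.numeric(box),
      coords = wrapped, unwrapped = as.matrix(unwrapped),
      labels = as.character(labels))
}

#' Wrap coordinates into the half-open periodic box
#'
#' @param coords n x 3 matrix, nm.
#' @param box three edge lengths, nm.
#' @return n x 3 matrix with every coordinate in `[0, L)`.
#' @export
wrapCoords <- function(coords, box) {
  out <- sweep(coords, 2, box, function(x, L) x - floor(x / L) * L)
  ## guard against x == L from roundoff of tiny negatives
  for (ax in 1:3) out[out[, ax] >= box[ax], ax] <- 0
  dimnames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## TabularSeries: an ordered independent variable with named SI columns
## ---------------------------------------------------------------------------

#' TabularSeries: ordered tabular data with declared units
#'
#' Carrier for temperature-indexed series (enthalpy, volume, density,
#' diffusion ...).  The independent variable is strictly increasing with no
#' duplicates.  All values are stored in internal SI (per-molecule for molar
#' quantities); the original unit strings are retained for reporting.
#'
#' @slot x independent variable values, SI.
#' @slot xUnit declared unit of the independent variable (e.g. `"K"`).
#' @slot data data.frame of dependent columns, converted to SI.
#' @slot units named character vector of the declared (input) units.
#'
#' @aliases TabularSeries-class
#' @export TabularSeries
#' @exportClass TabularSeries
TabularSeries <- setClass("TabularSeries",
  representation(
    x = "numeric",
    xUnit = "character",
    data = "data.frame",
    units = "character"
  ),
  prototype(x = numeric(0), xUnit = "K",
            data = data.frame(), units = character(0))
)

setValidity("TabularSeries", function(object) {
  msg <- character(0)
  n <- length(object@x)
  if (n > 1 && any(diff(object@x) <= 0))
    msg <- c(msg, "independent variable must be strictly increasing (no duplicates)")
  if (nrow(object@data) != n)
    msg <- c(msg, "data must have one row per x value")
  if (length(msg)) msg else TRUE
})

#' Construct a TabularSeries from values already in conventional units
#'
#' @param x independent variable in unit `xUnit`.
#' @param xUnit unit string of `x`.
#' @param ... named dependent vectors.
#' @param units named character vector giving the unit of each dependent
#'   column; values are converted to SI on construction.
#' @return a [TabularSeries-class] object.
#' @export
makeSeries <- function(x, xUnit = "K", ..., units) {
  cols <- list(...)
  if (length(cols) == 0) stop("at least one dependent column is required")
  if (missing(units) || is.null(names(units)) ||
      !all(names(cols) %in% names(units)))
    stop("'units' must name a unit for every dependent column")
  ord <- order(x)
  xSI <- toSI(x, xUnit)[ord]
  if (anyDuplicated(xSI)) stop("duplicated values in the independent variable")
  df <- as.data.frame(lapply(names(cols), function(nm)
    toSI(cols[[nm]], units[[nm]])[ord]))
  names(df) <- names(cols)
  new("TabularSeries", x = xSI, xUnit = xUnit, data = df,
      units = units[names(cols)])
}

## ---------------------------------------------------------------------------
## MoleculeTemplate: rigid planar rhombus with partial charges
## ---------------------------------------------------------------------------

#' MoleculeTemplate: four-site rigid rhombus with partial charges
#'
#' The quasi-real rhombus-like molecule: four identical atoms at the
#' vertices of a rhombus (long-diagonal atoms at `(+-dLong/2, 0, 0)`,
#' short-diagonal atoms at `(0, +-dShort/2, 0)`), all four bonds of equal
#' length, and a permanent dipole created by opposite partial charges on
#' the short-diagonal atoms.
#'
#' @slot positions 4 x 3 matrix of atom positions, nm (molecular plane z = 0).
#' @slot charges four partial charges, units of the elementary charge e.
#' @slot bondLength bond length b, nm.
#' @slot dLong long diagonal, nm.
#' @slot dShort short diagonal, nm.
#' @slot metadata free-form list (e.g. force-field bookkeeping, atom mass);
#'   never evaluated by any analysis.
#'
#' @aliases MoleculeTemplate-class
#' @export MoleculeTemplate
#' @exportClass MoleculeTemplate
MoleculeTemplate <- setClass("MoleculeTemplate",
  representation(
    positions = "matrix",
    charges = "numeric",
    bondLength = "numeric",
    dLong = "numeric",
    dShort = "numeric",
    metadata = "list"
  )
)

setValidity("MoleculeTemplate", function(object) {
  msg <- character(0)
  if (!all(dim(object@positions) == c(4L, 3L)))
    msg <- c(msg, "positions must be a 4 x 3 matrix")
  if (length(object@charges) != 4L)
    msg <- c(msg, "exactly four charges are required")
  if (abs(sum(object@charges)) > 1e-12)
    msg <- c(msg, "net charge must be zero")
  ## all four bonds equal b (relative tolerance 1e-12)
  p <- object@positions
  bonds <- c(sqrt(sum((p[1, ] - p[3, ])^2)), sqrt(sum((p[3, ] - p[2, ])^2)),
             sqrt(sum((p[2, ] - p[4, ])^2)), sqrt(sum((p[4, ] - p[1, ])^2)))
  if (any(abs(bonds - object@bondLength) > 1e-12 * object@bondLength))
    msg <- c(msg, "all four bond lengths must equal bondLength")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CapillaryEnsemble / HeightField / FluctuationSpectrum / StiffnessEstimate
## ---------------------------------------------------------------------------

#' CapillaryEnsemble: synthetic interface height fields
#'
#' An ensemble of quasi-one-dimensional interface height fields `h(x)`
#' sampled from the equipartition capillary spectrum at a known (injected)
#' interfacial stiffness.  Each Fourier mode `n >= 1` is a zero-mean complex
#' Gaussian with ensemble variance `kB*T / (Lx*Lz*stiffness*q_n^2)`,
#' `q_n = 2*pi*n/Lx`; the zero mode is excluded so every sample has zero
#' mean height.
#'
#' @slot heights nSamples x M matrix of height fields, nm.
#' @slot x M uniform bin centers along the lateral axis, nm.
#' @slot Lx lateral length, nm.
#' @slot Lz interface thickness, nm.
#' @slot temperature K.
#' @slot stiffness injected stiffness, mJ/m^2 (ground truth).
#' @slot nModes number of Fourier modes populated.
#' @slot seed integer seed used.
#'
#' @aliases CapillaryEnsemble-class
#' @export CapillaryEnsemble
#' @exportClass CapillaryEnsemble
CapillaryEnsemble <- setClass("CapillaryEnsemble",
  representation(
    heights = "matrix", x = "numeric", Lx = "numeric", Lz = "numeric",
    temperature = "numeric", stiffness = "numeric", nModes = "integer",
    seed = "integer"
  )
)

setValidity("CapillaryEnsemble", function(object) {
  msg <- character(0)
  if (ncol(object@heights) != length(object@x))
    msg <- c(msg, "heights must have one column per bin")
  if (object@stiffness <= 0) msg <- c(msg, "stiffness must be positive")
  if (object@nModes >= length(object@x) / 2)
    msg <- c(msg, "nModes must be below the Nyquist mode M/2")
  if (length(msg)) msg else TRUE
})

#' HeightField: one interface height field h(x)
#'
#' @slot x uniform capillary bin centers, nm.
#' @slot h interface heights at the bin centers, nm (mean removed before
#'   spectra).
#' @slot time frame time, ps.
#'
#' @aliases HeightField-class
#' @export HeightField
#' @exportClass HeightField
HeightField <- setClass("HeightField",
  representation(x = "numeric", h = "numeric", time = "numeric"),
  prototype(time = 0)
)

setValidity("HeightField", function(object) {
  if (length(object@x) != length(object@h))
    "x and h must have equal length" else TRUE
})

#' FluctuationSpectrum: averaged interface fluctuation power spectrum
#'
#' Wavenumbers `q_n = 2*pi*n/Lx` and the ensemble/time averaged squared
#' Fourier amplitudes of the interface height fields, with the forward
#' transform convention `h(q_n) = (1/M) * sum_j h(x_j) exp(-i q_n x_j)`.
#'
#' @slot q strictly increasing wavenumbers, nm^-1.
#' @slot s2 averaged `<|h(q)|^2>` per mode, nm^2 (all values >= 0).
#' @slot nFields number of height fields averaged.
#' @slot Lx lateral length, nm.
#' @slot Lz interface thickness, nm.
#'
#' @aliases FluctuationSpectrum-class
#' @export FluctuationSpectrum
#' @exportClass FluctuationSpectrum
FluctuationSpectrum <- setClass("FluctuationSpectrum",
  representation(q = "numeric", s2 = "numeric", nFields = "integer",
                 Lx = "numeric", Lz = "numeric")
)

setValidity("FluctuationSpectrum", function(object) {
  msg <- character(0)
  if (length(object@q) != length(object@s2))
    msg <- c(msg, "q and s2 must have equal length")
  if (length(object@q) > 1 && any(diff(object@q) <= 0))
    msg <- c(msg, "q must be strictly increasing")
  if (any(object@s2 < 0)) msg <- c(msg, "spectral values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' StiffnessEstimate: CFM interfacial stiffness from a fixed-slope fit
#'
#' Result of fitting `ln <|h(q)|^2> = c - 2 ln q` over a mode window and
#' inverting the equipartition relation for the stiffness.  The
#' unconstrained log-log slope over the same window is kept as a quality
#' check; a deviation beyond `qcTolerance` from -2 raises a recorded (not
#' fatal) warning.
#'
#' @slot stiffness estimated stiffness, mJ/m^2.
#' @slot se standard error, mJ/m^2.
#' @slot window integer mode indices used.
#' @slot intercept fitted intercept `c` (natural log, SI).
#' @slot qcSlope unconstrained slope over the window.
#' @slot qcTolerance allowed |qcSlope + 2| before flagging.
#' @slot qcWarning TRUE when the QC slope deviates beyond tolerance.
#'
#' @aliases StiffnessEstimate-class
#' @export StiffnessEstimate
#' @exportClass StiffnessEstimate
StiffnessEstimate <- setClass("StiffnessEstimate",
  representation(stiffness = "numeric", se = "numeric", window = "integer",
                 intercept = "numeric", qcSlope = "numeric",
                 qcTolerance = "numeric", qcWarning = "logical")
)

setValidity("StiffnessEstimate", function(object) {
  if (object@stiffness <= 0) "stiffness must be positive" else TRUE
})

#' InterfaceProfileFit: two-interface tanh fit of an order-parameter profile
#'
#' Parameters of the slab profile
#' `o(y) = oL + (oS - oL)/2 * [tanh((y - h1)/delta1) - tanh((y - h2)/delta2)]`
#' fitted to a binned order-parameter profile along the interface normal.
#' Canonical ordering: `oS > oL`, `h1 < h2`, positive widths.
#'
#' @slot oS bulk solid order-parameter level.
#' @slot oL bulk liquid level.
#' @slot h1,h2 interface positions along the normal, nm.
#' @slot delta1,delta2 effective interface widths, nm.
#' @slot residual residual norm of the least-squares fit.
#' @slot form profile form used, `"slab"` (sign-corrected) or `"printed"`.
#'
#' @aliases InterfaceProfileFit-class
#' @export InterfaceProfileFit
#' @exportClass InterfaceProfileFit
InterfaceProfileFit <- setClass("InterfaceProfileFit",
  representation(oS = "numeric", oL = "numeric", h1 = "numeric",
                 h2 = "numeric", delta1 = "numeric", delta2 = "numeric",
                 residual = "numeric", form = "character")
)

setValidity("InterfaceProfileFit", function(object) {
  msg <- character(0)
  if (object@oS <= object@oL) msg <- c(msg, "oS must exceed oL")
  if (object@delta1 <= 0 || object@delta2 <= 0)
    msg <- c(msg, "interface widths must be positive")
  if (object@h1 >= object@h2) msg <- c(msg, "h1 must precede h2")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Neighbor lists and order fields
## ---------------------------------------------------------------------------

#' NeighborList: per-molecule neighbors with minimum-image displacements
#'
#' @slot idx list of integer neighbor-id vectors, ordered by distance.
#' @slot disp list of k x 3 matrices of minimum-image displacement vectors
#'   (nm) from each molecule to its neighbors, same order as `idx`.
#' @slot criterion list describing the neighbor rule: either
#'   `list(type = "cutoff", cutoff = r)` or `list(type = "knn", k = k)`.
#'
#' @aliases NeighborList-class
#' @export NeighborList
#' @exportClass NeighborList
NeighborList <- setClass("NeighborList",
  representation(idx = "list", disp = "list", criterion = "list")
)

setValidity("NeighborList", function(object) {
  if (length(object@idx) != length(object@disp))
    "idx and disp must be parallel lists" else TRUE
})

#' OrderField: per-molecule rotationally invariant order parameter
#'
#' Steinhardt bond-orientational order parameter `q_l` (or its
#' neighbor-averaged variant) evaluated at molecular geometric centers.
#' Values lie in `[0, 1]`; molecules without neighbors are flagged and
#' excluded from interface profiles.
#'
#' @slot values per-molecule order-parameter values in `[0, 1]` (`NA` for
#'   flagged molecules).
#' @slot l spherical-harmonic order used (even).
#' @slot averaged TRUE for the neighbor-averaged variant.
#' @slot criterion the neighbor criterion used.
#' @slot flagged logical vector marking isolated molecules.
#'
#' @aliases OrderField-class
#' @export OrderField
#' @exportClass OrderField
OrderField <- setClass("OrderField",
  representation(values = "numeric", l = "integer", averaged = "logical",
                 criterion = "list", flagged = "logical")
)

setValidity("OrderField", function(object) {
  ok <- object@values[!object@flagged]
  if (any(ok < -1e-9 | ok > 1 + 1e-9, na.rm = TRUE))
    "order-parameter values must lie in [0, 1]" else TRUE
})

## ---------------------------------------------------------------------------
## Thermodynamics containers
## ---------------------------------------------------------------------------

#' ThermoCurves: liquid and crystal thermodynamic branches
#'
#' Temperature grids of the liquid and crystal per-molecule enthalpy and
#' number density, together with the melting temperature and melting
#' enthalpy.  The grid covers temperatures up to `Tm` (its last point), and
#' `dHm = hLiq(Tm) - hCr(Tm) > 0`.
#'
#' @slot temperature strictly increasing grid, K, ending at `Tm`.
#' @slot hLiq,hCr per-molecule enthalpy branches, J/molecule.
#' @slot rhoLiq,rhoCr number densities, nm^-3.
#' @slot Tm melting temperature, K.
#' @slot dHm melting enthalpy, J/molecule.
#'
#' @aliases ThermoCurves-class
#' @export ThermoCurves
#' @exportClass ThermoCurves
ThermoCurves <- setClass("ThermoCurves",
  representation(temperature = "numeric", hLiq = "numeric", hCr = "numeric",
                 rhoLiq = "numeric", rhoCr = "numeric", Tm = "numeric",
                 dHm = "numeric")
)

setValidity("ThermoCurves", function(object) {
  msg <- character(0)
  Tg <- object@temperature
  n <- length(Tg)
  if (n < 2) msg <- c(msg, "temperature grid needs at least two points")
  if (n > 1 && any(diff(Tg) <= 0))
    msg <- c(msg, "temperature grid must be strictly increasing")
  lens <- c(length(object@hLiq), length(object@hCr),
            length(object@rhoLiq), length(object@rhoCr))
  if (any(lens != n)) msg <- c(msg, "all branches must match the grid length")
  if (n >= 1 && abs(Tg[n] - object@Tm) > 1e-9)
    msg <- c(msg, "grid must end at Tm")
  if (object@dHm <= 0) msg <- c(msg, "melting enthalpy must be positive")
  if (n >= 1 &&
      abs((object@hLiq[n] - object@hCr[n]) - object@dHm) >
        1e-9 * max(object@dHm, 1e-30))
    msg <- c(msg, "hLiq(Tm) - hCr(Tm) must equal dHm")
  if (length(msg)) msg else TRUE
})

#' DrivingForce: entropy difference and crystallization driving force
#'
#' `dS(T)` is the liquid-minus-crystal entropy difference, `dG(T)` the
#' per-molecule driving force `-integral_Tm^T dS dT'` (zero at `Tm`,
#' positive below it for positive `dS`), and `dGv(T) = dG * rhoCr` the
#' driving force per unit volume entering the nucleation barrier.
#'
#' @slot temperature grid, K.
#' @slot dS entropy difference, J/K/molecule.
#' @slot dG driving force, J/molecule.
#' @slot dGv driving force per volume, J/m^3.
#'
#' @aliases DrivingForce-class
#' @export DrivingForce
#' @exportClass DrivingForce
DrivingForce <- setClass("DrivingForce",
  representation(temperature = "numeric", dS = "numeric", dG = "numeric",
                 dGv = "numeric")
)

#' GammaCurve: Turnbull-scaled interfacial free energy
#'
#' @slot temperature grid, K.
#' @slot gamma interfacial free energy gamma(T), mJ/m^2; equals `gammaM`
#'   exactly at `Tm`.
#' @slot gammaM melting-point interfacial free energy, mJ/m^2.
#'
#' @aliases GammaCurve-class
#' @export GammaCurve
#' @exportClass GammaCurve
GammaCurve <- setClass("GammaCurve",
  representation(temperature = "numeric", gamma = "numeric",
                 gammaM = "numeric")
)

## ---------------------------------------------------------------------------
## Dynamics containers
## ---------------------------------------------------------------------------

#' VFTParams: Vogel-Fulcher-Tammann parameters for D(T)
#'
#' Parameterization `log10(1/D) = log10(1/D0) + log10(e) * B/(T - T0)` with
#' `D0` in m^2/s.  Evaluation requires `T > T0`.
#'
#' @slot log10invD0 `log10(1/D0)`, D0 in m^2/s.
#' @slot B activation parameter, K (> 0).
#' @slot T0 Vogel temperature, K (>= 0).
#' @slot covariance 3 x 3 covariance matrix of the fitted parameters
#'   (zero matrix when constructed directly).
#'
#' @aliases VFTParams-class
#' @export VFTParams
#' @exportClass VFTParams
VFTParams <- setClass("VFTParams",
  representation(log10invD0 = "numeric", B = "numeric", T0 = "numeric",
                 covariance = "matrix"),
  prototype(covariance = matrix(0, 3, 3))
)

setValidity("VFTParams", function(object) {
  msg <- character(0)
  if (object@B <= 0) msg <- c(msg, "B must be positive")
  if (object@T0 < 0) msg <- c(msg, "T0 must be >= 0")
  if (!all(dim(object@covariance) == c(3L, 3L)))
    msg <- c(msg, "covariance must be 3 x 3")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CNT rate curves
## ---------------------------------------------------------------------------

#' CNTResult: assembled nucleation and growth rate curves
#'
#' Per-temperature classical-nucleation-theory quantities: the
#' Turnbull-scaled interfacial free energy, driving force per molecule and
#' per volume, nucleation barrier, VFT diffusion coefficient, kinetic
#' prefactor, nucleation rate `N`, growth rate `U`, and the
#' diffusion-normalized diagnostic `N/D`.
#'
#' @slot temperature grid, K.
#' @slot gamma gamma(T), mJ/m^2.
#' @slot dG driving force, J/molecule.
#' @slot dGv driving force per volume, J/m^3.
#' @slot dW nucleation barrier, J (`Inf` where `dGv = 0`).
#' @slot D diffusion coefficient, m^2/s.
#' @slot aU kinetic prefactor `A_U = D * a / lambda^2`, m/s.
#' @slot N nucleation rate, nm^-3 s^-1.
#' @slot U growth rate, m/s.
#' @slot nOverD `N/D`, (nm^-3 s^-1) / (m^2/s).
#' @slot argmaxN,argmaxU grid temperatures maximizing N and U, K.
#'
#' @aliases CNTResult-class
#' @export CNTResult
#' @exportClass CNTResult
CNTResult <- setClass("CNTResult",
  representation(temperature = "numeric", gamma = "numeric", dG = "numeric",
                 dGv = "numeric", dW = "numeric", D = "numeric",
                 aU = "numeric", N = "numeric", U = "numeric",
                 nOverD = "numeric", argmaxN = "numeric", argmaxU = "numeric")
)

setValidity("CNTResult", function(object) {
  msg <- character(0)
  if (any(object@N < 0)) msg <- c(msg, "nucleation rate must be >= 0")
  if (any(object@U < 0)) msg <- c(msg, "growth rate must be >= 0")
  if (length(msg)) msg else TRUE
})
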