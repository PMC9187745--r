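## Crystallization driving force by entropy integration, Turnbull scaling
## of the interfacial free energy, and first-order transition detection.

#' Liquid-crystal entropy difference by entropy integration
#'
#' Integrates the classical relation `T = (dH/dS)_p` from the melting
#' boundary condition `dSm = dHm/Tm` downward:
#' `dS(T) = dSm + integral_Tm^T (1/T') d(dH)/dT' dT'` with
#' `dH(T) = hLiq(T) - hCr(T)`.  The enthalpy derivative uses centered
#' finite differences (one-sided at the grid ends, optionally after a
#' smoothing polynomial), the integral the trapezoid rule on the grid
#' (non-uniform grids are supported).
#'
#' @param curves a [ThermoCurves-class].
#' @param smoothDegree if positive, degree of a polynomial fitted to
#'   `dH(T)` before differentiation (for noisy simulation enthalpies);
#'   0 (default) differentiates the raw branches.
#' @return a [TabularSeries-class] on the same grid with column `dS`
#'   (J/K/molecule).
#' @examples
#' tc <- makeThermoCurves(Tm = 200, dHm = 1e-20, Tgrid = seq(100, 200, 1),
#'                        cpLiq = 4.1e-23, cpCr = 4.1e-23)
#' seriesColumn(deltaEntropy(tc), "dS")[1]   # = dHm/Tm everywhere
#' @export
deltaEntropy <- function(curves, smoothDegree = 0L) {
  stopifnot(is(curves, "ThermoCurves"))
  Tg <- curves@temperature
  if (any(Tg <= 0)) stop("temperature grid must be strictly positive")
  dH <- curves@hLiq - curves@hCr
  if (smoothDegree > 0) {
    fit <- stats::lm(dH ~ poly(Tg, smoothDegree, raw = TRUE))
    dH <- stats::fitted(fit)
  }
  dHdT <- .gridDerivative(Tg, dH)
  integrand <- dHdT / Tg
  dSm <- curves@dHm / curves@Tm
  ## I(T_i) = integral_Tm^{T_i} integrand dT'  (zero at the last point, Tm)
  n <- length(Tg)
  segment <- 0.5 * (integrand[-1] + integrand[-n]) * diff(Tg)
  I <- -rev(cumsum(rev(c(segment, 0))))
  makeSeries(Tg, xUnit = "K", dS = dSm + I, units = c(dS = "J/K"))
}

.gridDerivative <- function(x, y) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2)
    d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  d
}

#' Crystallization driving force from the entropy difference
#'
#' `dG(T) = -integral_Tm^T dS(T') dT'` by the trapezoid rule, integrated
#' from `Tm` downward, so `dG(Tm) = 0` exactly and `dG > 0` below `Tm`
#' whenever `dS > 0` on the interval.  The volumetric driving force
#' entering the nucleation barrier is `dGv(T) = dG(T) * rhoCr(T)` in
#' J/m^3.
#'
#' @param dS entropy-difference series from [deltaEntropy()] (or any
#'   [TabularSeries-class] with a `dS` column, J/K/molecule, ending at
#'   `Tm`).
#' @param Tm melting temperature, K (must be the last grid point).
#' @param rhoCr crystal number density, nm^-3: scalar or vector on the
#'   grid.
#' @return a [DrivingForce-class].
#' @export
drivingForce <- function(dS, Tm, rhoCr) {
  stopifnot(is(dS, "TabularSeries"))
  Tg <- fromSI(seriesX(dS), dS@xUnit)
  if (abs(Tg[length(Tg)] - Tm) > 1e-9)
    stop("the entropy grid must end at Tm")
  s <- seriesColumn(dS, "dS")
  n <- length(Tg)
  segment <- 0.5 * (s[-1] + s[-n]) * diff(Tg)
  dG <- rev(cumsum(rev(c(segment, 0))))   # = integral_T^Tm dS dT'
  rho <- rep_len(as.numeric(rhoCr), n)
  new("DrivingForce", temperature = Tg, dS = s, dG = dG,
      dGv = dG * toSI(rho, "nm^-3"))
}

#' Convenience: driving force directly from thermodynamic branches
#'
#' @param curves a [ThermoCurves-class].
#' @param smoothDegree passed to [deltaEntropy()].
#' @return a [DrivingForce-class].
#' @export
drivingForceFromCurves <- function(curves, smoothDegree = 0L) {
  drivingForce(deltaEntropy(curves, smoothDegree), curves@Tm, curves@rhoCr)
}

#' Turnbull temperature scaling of the interfacial free energy
#'
#' `gamma(T) = gammaM * (rhoCr(T)/rhoCr(Tm))^(2/3) * (dH(T)/dHm)`, with
#' `gamma(Tm) = gammaM` exactly.  A non-positive enthalpy difference
#' anywhere on the grid is unphysical below `Tm` and rejected.
#'
#' @param gammaM melting-point interfacial free energy, mJ/m^2 (> 0).
#' @param curves a [ThermoCurves-class].
#' @return a [GammaCurve-class] (gamma in mJ/m^2).
#' @export
turnbullGamma <- function(gammaM, curves) {
  stopifnot(is(curves, "ThermoCurves"))
  if (!is.finite(gammaM) || gammaM <= 0) stop("gammaM must be positive")
  dH <- curves@hLiq - curves@hCr
  if (any(dH <= 0))
    stop("non-positive enthalpy difference on the grid (unphysical below Tm)")
  n <- length(curves@temperature)
  g <- gammaM * (curves@rhoCr / curves@rhoCr[n])^(2 / 3) * (dH / curves@dHm)
  new("GammaCurve", temperature = curves@temperature, gamma = g,
      gammaM = gammaM)
}

#' Detect a first-order transition in a volume curve
#'
#' Scans an ordered per-molecule volume series for single-step changes and
#' returns the largest one exceeding `minJump` (a rapid volume change
#' marks melting on heating or crystallization on cooling).  The reported
#' temperature is the grid point at which the new branch is first
#' attained.  Hysteresis semantics (heating vs cooling) belong to the
#' caller.
#'
#' @param volume a [TabularSeries-class] with column `V` (per-molecule
#'   volume) on a temperature grid.
#' @param minJump minimum step size to qualify, nm^3.
#' @return list with `temperature` (K) and `jump` (signed, nm^3), or
#'   `NULL` when no step qualifies.
#' @examples
#' v <- makeVolumeCurve(seq(10, 270, 5), vLow = 0.086, vHigh = 0.094,
#'                      jumpAt = 220)
#' detectTransition(v, minJump = 0.004)
#' @export
detectTransition <- function(volume, minJump) {
  stopifnot(is(volume, "TabularSeries"))
  Tg <- fromSI(seriesX(volume), volume@xUnit)
  v <- fromSI(seriesColumn(volume, "V"), "nm^3")
  if (length(v) < 2) return(NULL)
  steps <- diff(v)
  k <- which.max(abs(steps))
  if (abs(steps[k]) <= minJump) return(NULL)
  list(temperature = Tg[k + 1L], jump = steps[k])
}
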