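## Assembly of the CNT nucleation-rate and growth-rate curves.

#' CNT nucleation barrier
#'
#' `dW = (16/3) * gamma^3 / dGv^2`: the free-energy cost of the critical
#' nucleus set by the interfacial penalty against the volumetric driving
#' force.  `dGv = 0` (at the melting point) gives `dW = +Inf`, which
#' downstream suppresses the nucleation rate to exactly zero.
#'
#' @param gamma interfacial free energy, J/m^2 (> 0); vectorized.
#' @param dGv driving force per volume, J/m^3 (>= 0).
#' @return barrier, J.
#' @examples
#' nucleationBarrier(1, 1)   # 16/3 in reduced units
#' @export
nucleationBarrier <- function(gamma, dGv) {
  if (any(!is.finite(gamma) | gamma <= 0)) stop("gamma must be positive")
  dims <- .dimProduct(.dimPower(unitDimensions("J/m^2"), 3),
                      .dimPower(unitDimensions("J/m^3"), -2))
  stopifnot(.dimEqual(dims, unitDimensions("J")))
  ifelse(dGv == 0, Inf, (16 / 3) * gamma^3 / dGv^2)
}

#' CNT nucleation rate
#'
#' `N = rhoLiq^(4/3) * sqrt(gamma/(kB*T)) * D * exp(-dW/(kB*T))`,
#' evaluated in SI and reported in nm^-3 s^-1.  The unit algebra is
#' audited on every call: the composed quantity must reduce to inverse
#' volume times inverse time before conversion.
#'
#' @param rhoLiq liquid number density, m^-3.
#' @param gamma interfacial free energy, J/m^2.
#' @param T temperature, K.
#' @param D diffusion coefficient, m^2/s.
#' @param dW nucleation barrier, J (`+Inf` allowed: gives N = 0).
#' @return nucleation rate, nm^-3 s^-1.
#' @export
nucleationRate <- function(rhoLiq, gamma, T, D, dW) {
  if (any(rhoLiq <= 0 | gamma <= 0 | T <= 0 | D < 0))
    stop("rhoLiq, gamma and T must be positive and D >= 0")
  if (any(dW < 0)) stop("the nucleation barrier cannot be negative")
  dims <- .dimProduct(.dimPower(unitDimensions("m^-3"), 4 / 3),
                      .dimPower(.dimProduct(unitDimensions("J/m^2"),
                                            .dimPower(unitDimensions("J"), -1)),
                                1 / 2),
                      unitDimensions("m^2/s"))
  stopifnot(.dimEqual(dims, unitDimensions("m^-3*s^-1")))
  nSI <- rhoLiq^(4 / 3) * sqrt(gamma / (kBoltzmann * T)) * D *
    exp(-dW / (kBoltzmann * T))
  fromSI(nSI, "nm^-3*s^-1")
}

#' CNT crystal growth rate
#'
#' `U = A_U * f * [1 - exp(-dG/(kB*T))]` with the kinetic prefactor
#' `A_U = D * a / lambda^2`, `a = rhoCr^(-1/3)` the crystal lattice
#' spacing and `lambda = rhoLiq^(-1/3)` the jump distance.  `dG = 0`
#' (melting point) gives `U = 0` exactly; negative `dG` (above melting)
#' is clamped to `U = 0` with a warning.
#'
#' @param D diffusion coefficient, m^2/s.
#' @param rhoCr,rhoLiq crystal/liquid number densities, m^-3.
#' @param dG driving force per molecule, J.
#' @param T temperature, K.
#' @param f growth-mechanism factor in (0, 1]; 1 for normal growth.
#' @return growth rate, m/s.
#' @export
growthRate <- function(D, rhoCr, rhoLiq, dG, T, f = 1) {
  if (any(rhoCr <= 0 | rhoLiq <= 0)) stop("densities must be positive")
  if (any(f <= 0 | f > 1)) stop("f must lie in (0, 1]")
  dims <- .dimProduct(unitDimensions("m^2/s"),
                      .dimPower(unitDimensions("m^-3"), -1 / 3),
                      .dimPower(.dimPower(unitDimensions("m^-3"), -1 / 3), -2))
  stopifnot(.dimEqual(dims, unitDimensions("m/s")))
  a <- rhoCr^(-1 / 3)
  lambda <- rhoLiq^(-1 / 3)
  aU <- D * a / lambda^2
  u <- aU * f * (1 - exp(-dG / (kBoltzmann * T)))
  if (any(dG < 0)) {
    warning("negative driving force (above melting): growth rate clamped to 0")
    u[dG < 0] <- 0
  }
  u
}

#' Assemble the CNT rate curves on a temperature grid
#'
#' Composes the whole downstream pipeline: Turnbull-scaled `gamma(T)`
#' (the scaled curve, not the constant `gammaM`, enters both the barrier
#' and the `sqrt(gamma/kBT)` prefactor; `gammaMode = "constant"` is
#' available for comparison), the entropy-integrated driving force, the
#' VFT diffusion coefficient, the nucleation barrier, and the nucleation
#' and growth rates, and locates the temperatures of maximal N and U.
#'
#' @param curves a [ThermoCurves-class].
#' @param gammaM melting-point interfacial free energy, mJ/m^2.
#' @param vft a [VFTParams-class] for D(T).
#' @param Tgrid evaluation grid, K; defaults to the curve grid.  Must lie
#'   within `(T0, Tm]`; thermodynamic quantities are linearly
#'   interpolated onto it.
#' @param f growth-mechanism factor (default 1, normal growth).
#' @param gammaMode `"turnbull"` (default) or `"constant"`.
#' @param smoothDegree passed to [deltaEntropy()].
#' @return a [CNTResult-class].
#' @examples
#' tc <- makeThermoCurves(Tm = 150, dHm = 3.1e-21, Tgrid = seq(60, 150, 2))
#' vft <- VFTParams(log10invD0 = 10.68, B = 520, T0 = 35)
#' res <- rateCurves(tc, gammaM = 2.53, vft = vft)
#' @export
rateCurves <- function(curves, gammaM, vft, Tgrid = NULL, f = 1,
                       gammaMode = c("turnbull", "constant"),
                       smoothDegree = 0L) {
  stopifnot(is(curves, "ThermoCurves"), is(vft, "VFTParams"))
  gammaMode <- match.arg(gammaMode)
  Tc <- curves@temperature
  if (is.null(Tgrid)) Tgrid <- Tc[Tc > vft@T0]
  Tgrid <- sort(unique(as.numeric(Tgrid)))
  if (any(Tgrid <= vft@T0) || any(Tgrid > curves@Tm + 1e-9))
    stop("Tgrid must lie within (T0, Tm]")
  interp <- function(y) stats::approx(Tc, y, xout = Tgrid, rule = 2)$y
  df <- drivingForceFromCurves(curves, smoothDegree)
  gc <- turnbullGamma(gammaM, curves)
  gammaT <- if (gammaMode == "turnbull") interp(gc@gamma)
            else rep(gammaM, length(Tgrid))
  dG <- interp(df@dG)
  dGv <- interp(df@dGv)
  rhoLiqSI <- toSI(interp(curves@rhoLiq), "nm^-3")
  rhoCrSI <- toSI(interp(curves@rhoCr), "nm^-3")
  gammaSI <- toSI(gammaT, "mJ/m^2")
  D <- evalVFT(vft, Tgrid)
  dW <- nucleationBarrier(gammaSI, dGv)
  N <- nucleationRate(rhoLiqSI, gammaSI, Tgrid, D, dW)
  U <- growthRate(D, rhoCrSI, rhoLiqSI, pmax(dG, 0), Tgrid, f)
  aU <- D * rhoCrSI^(-1 / 3) / rhoLiqSI^(-2 / 3)
  new("CNTResult", temperature = Tgrid, gamma = gammaT, dG = dG, dGv = dGv,
      dW = dW, D = D, aU = aU, N = N, U = U, nOverD = N / D,
      argmaxN = Tgrid[which.max(N)], argmaxU = Tgrid[which.max(U)])
}

#' Nucleation rate divided by the diffusion coefficient
#'
#' The diagnostic `N/D`: because CNT makes both N and U exactly linear in
#' D, `N/D` is independent of the diffusion coefficient and isolates the
#' thermodynamic content of the nucleation-rate prediction.  Two systems
#' differing only in their dynamics have identical `N/D` curves.
#'
#' @param result a [CNTResult-class].
#' @return data.frame with `T_K` and `N_over_D` (the stored pointwise
#'   ratio, (nm^-3 s^-1)/(m^2/s)).
#' @export
nOverD <- function(result) {
  stopifnot(is(result, "CNTResult"))
  data.frame(T_K = result@temperature, N_over_D = result@nOverD)
}

#' Plot the nucleation and growth rate curves on log scales
#'
#' @param x a [CNTResult-class].
#' @param y unused.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @aliases plot,CNTResult,missing-method
#' @export
setMethod("plot", signature(x = "CNTResult", y = "missing"),
  function(x, ...) {
    ok <- x@N > 0
    graphics::par(mfrow = c(1, 2))
    graphics::plot(x@temperature[ok], x@N[ok], log = "y", type = "l",
                   xlab = "T [K]", ylab = "N [1/(nm^3 s)]", ...)
    okU <- x@U > 0
    graphics::plot(x@temperature[okU], x@U[okU], log = "y", type = "l",
                   xlab = "T [K]", ylab = "U [m/s]", ...)
    graphics::par(mfrow = c(1, 1))
    invisible(x)
  })
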