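## Mean-square displacement, diffusion constants, and the VFT law.

#' Mean-square displacement of a trajectory
#'
#' Time-origin-averaged MSD: `MSD(tau)` is the squared displacement at lag
#' `tau` averaged over all particles and all time origins (sliding
#' window), computed with the FFT autocorrelation identity so the cost is
#' `O(F log F)` per particle axis.  Requires unwrapped coordinates; when
#' only wrapped coordinates exist they are accepted only if no per-step
#' displacement exceeds half a box edge (otherwise the wrap is ambiguous
#' and an error is raised).
#'
#' @param trajectory list of [Frame-class] objects at uniform time
#'   spacing (>= 2 frames).
#' @param useUnwrapped use the unwrapped coordinates (default TRUE).
#' @param maxLag largest lag (in frames) reported; default half the
#'   trajectory length.
#' @return a [TabularSeries-class]: lag time (ps) vs `MSD` (nm^2),
#'   starting at lag 1.
#' @examples
#' trj <- makeBrownianTrajectory(0.001, 20, 100, dt = 1, seed = 5)
#' m <- msd(trj)
#' @export
msd <- function(trajectory, useUnwrapped = TRUE, maxLag = NULL) {
  F <- length(trajectory)
  if (F < 2) stop("at least two frames are required")
  times <- vapply(trajectory, frameTime, numeric(1))
  dts <- diff(times)
  if (any(abs(dts - dts[1]) > 1e-9 * max(abs(dts[1]), 1e-12)))
    stop("non-uniform time spacing between frames")
  dt <- dts[1]
  n <- nMolecules(trajectory[[1]])
  getCoords <- function(fr) {
    if (useUnwrapped && nrow(unwrappedPositions(fr)) == n)
      unwrappedPositions(fr)
    else positions(fr)
  }
  usingUnwrapped <- useUnwrapped &&
    all(vapply(trajectory, function(fr)
      nrow(unwrappedPositions(fr)) == n, logical(1)))
  ## F x n matrices per axis
  if (is.null(maxLag)) maxLag <- max(1L, floor((F - 1) / 2))
  maxLag <- min(as.integer(maxLag), F - 1L)
  acc <- numeric(maxLag)
  box <- boxEdges(trajectory[[1]])
  for (ax in 1:3) {
    X <- vapply(trajectory, function(fr) getCoords(fr)[, ax], numeric(n))
    X <- if (n == 1L) matrix(X, ncol = 1L) else t(X)     # F x n
    if (!usingUnwrapped) {
      stepMax <- max(abs(diff(X)))
      if (stepMax > box[ax] / 2)
        stop("wrapped-only coordinates with per-step displacement ",
             "exceeding L/2; provide unwrapped coordinates")
    }
    sq <- X^2
    cumHead <- rbind(0, apply(sq, 2, cumsum))           # (F+1) x n
    Q <- cumHead[F + 1L, ]
    ## autocorrelation S2(tau) = sum_t x(t) x(t+tau) via zero-padded FFT
    pad <- 2L * stats::nextn(F, 2)
    Xp <- rbind(X, matrix(0, pad - F, n))
    A <- stats::mvfft(Xp)
    S2 <- Re(stats::mvfft(A * Conj(A), inverse = TRUE))[1:F, , drop = FALSE] /
      pad
    for (tau in seq_len(maxLag)) {
      s1 <- 2 * Q - cumHead[tau + 1L, ] - (Q - cumHead[F - tau + 1L, ])
      acc[tau] <- acc[tau] + sum(s1 - 2 * S2[tau + 1L, ]) / ((F - tau) * n)
    }
  }
  makeSeries((seq_len(maxLag)) * dt, xUnit = "ps", MSD = acc,
             units = c(MSD = "nm^2"))
}

#' Diffusion constant from an MSD series (Einstein relation)
#'
#' Fits a straight line to `MSD(t)` over the requested lag window and
#' returns `D = slope/6` (three dimensions).  The local log-log slope of
#' the MSD over the window is reported as a quality check: a diffusive
#' window has slope 1 (tolerance 0.1); ballistic or sub-diffusive windows
#' trigger a recorded warning, not an error.
#'
#' @param msdSeries output of [msd()] (lag ps vs MSD nm^2).
#' @param fitWindow length-2 lag-time range (ps) to fit; default the
#'   second half of the available lags.
#' @return list with `D` (m^2/s), `slope` (nm^2/ps), `qcSlope` (log-log),
#'   `qcWarning` (logical).
#' @export
diffusionFromMsd <- function(msdSeries, fitWindow = NULL) {
  stopifnot(is(msdSeries, "TabularSeries"))
  t <- fromSI(seriesX(msdSeries), "ps")
  m <- fromSI(seriesColumn(msdSeries, "MSD"), "nm^2")
  if (is.null(fitWindow)) fitWindow <- c(t[ceiling(length(t) / 2)], max(t))
  sel <- t >= fitWindow[1] & t <= fitWindow[2]
  if (sum(sel) < 2) stop("fit window contains fewer than 2 lags")
  fit <- stats::lm(m[sel] ~ t[sel])
  slope <- stats::coef(fit)[[2]]
  pos <- sel & m > 0 & t > 0
  qc <- if (sum(pos) >= 2)
    stats::coef(stats::lm(log(m[pos]) ~ log(t[pos])))[[2]] else NA_real_
  qcWarn <- is.na(qc) || abs(qc - 1) > 0.1
  if (qcWarn)
    warning(sprintf("MSD window not diffusive: log-log slope %.2f", qc))
  list(D = toSI(slope / 6, "nm^2/ps"), slope = slope, qcSlope = qc,
       qcWarning = qcWarn)
}

.vftModel <- function(T, log10invD0, B, T0)
  log10invD0 + log10(exp(1)) * B / (T - T0)

#' Fit the Vogel-Fulcher-Tammann law to a diffusion series
#'
#' Nonlinear least squares of
#' `log10(1/D) = log10(1/D0) + log10(e) * B/(T - T0)` against the series,
#' fitted in log10(1/D) space (which weights decades evenly).
#' Initialization: `T0 = 0.8 * min(T)`, `B` from the two-point slope of
#' the extreme temperatures.  `T0` is bounded to `[0, min(T))`; an
#' optimum pinned at `min(T)` is rejected as an invalid fit.  Noiseless
#' VFT data is recovered to machine precision.
#'
#' @param series a [TabularSeries-class] with column `D` (m^2/s) on a
#'   temperature grid spanning at least 20 K, >= 4 points.
#' @return a [VFTParams-class] with the parameter covariance.
#' @examples
#' d <- makeVFTDiffusion(1e-11, 520, 35, seq(140, 220, 10))
#' fitVFT(d)
#' @export
fitVFT <- function(series) {
  stopifnot(is(series, "TabularSeries"))
  T <- fromSI(seriesX(series), series@xUnit)
  D <- seriesColumn(series, "D")
  if (any(D <= 0)) stop("diffusion values must be positive")
  if (length(T) < 4) stop("at least 4 points are required")
  if (diff(range(T)) < 20) stop("temperature spread must be >= 20 K")
  y <- -log10(D)
  T0i <- 0.8 * min(T)
  i1 <- which.min(T); i2 <- which.max(T)
  Bi <- (y[i1] - y[i2]) /
    (log10(exp(1)) * (1 / (T[i1] - T0i) - 1 / (T[i2] - T0i)))
  if (!is.finite(Bi) || Bi <= 0) Bi <- 100
  ai <- y[i2] - log10(exp(1)) * Bi / (T[i2] - T0i)
  out <- minpack.lm::nls.lm(
    par = c(a = ai, B = Bi, T0 = T0i),
    lower = c(-Inf, 1e-12, 0), upper = c(Inf, Inf, min(T) - 1e-6),
    fn = function(p) y - .vftModel(T, p[1], p[2], p[3]),
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                         maxiter = 1000))
  if (out$info < 1 || out$info > 4)
    stop("VFT fit did not converge: ", out$message,
         " (residual sum of squares ", signif(out$deviance, 6), ")",
         call. = FALSE)
  cf <- out$par
  if (cf[["T0"]] >= min(T) - 1e-3)
    stop("invalid VFT fit: T0 reached the lowest data temperature")
  dof <- length(T) - 3L
  cov <- tryCatch({
    sigma2 <- if (dof > 0) out$deviance / dof else 0
    sigma2 * solve(out$hessian)
  }, error = function(e) matrix(0, 3, 3))
  if (any(!is.finite(cov))) cov <- matrix(0, 3, 3)
  new("VFTParams", log10invD0 = cf[["a"]], B = cf[["B"]], T0 = cf[["T0"]],
      covariance = unname(cov))
}

#' Evaluate the VFT law
#'
#' `D(T) = 10^-(log10(1/D0) + log10(e) * B/(T - T0))` in m^2/s; defined
#' only above the Vogel temperature.
#'
#' @param params a [VFTParams-class].
#' @param T temperatures, K (all `> T0`).
#' @return diffusion coefficients, m^2/s.
#' @export
evalVFT <- function(params, T) {
  stopifnot(is(params, "VFTParams"))
  if (any(T <= params@T0))
    stop("VFT is undefined at or below T0 = ", params@T0, " K")
  10^(-.vftModel(T, params@log10invD0, params@B, params@T0))
}
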