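## Capillary fluctuation method: interface localization via tanh profile
## fits per capillary, height-field assembly, fluctuation power spectrum,
## and the fixed-slope stiffness fit.

#' Bin a biphasic frame into capillaries and build order-parameter profiles
#'
#' Splits the box into capillaries (sections `[x, x + binWidth)` along the
#' lateral axis) and, within each, histogram-averages the order parameter
#' on a fixed grid along the interface normal.  Before binning, the normal
#' coordinate is cyclically shifted so the solid slab is contiguous and
#' centered (circular mean of positions weighted by order value), which
#' fixes the periodic-boundary ambiguity of the two interfaces: interface
#' 1 is always the low-normal-coordinate one.
#'
#' @param frame a [Frame-class] (quasi-1D geometry: thin axis much smaller
#'   than the lateral axis).
#' @param order an [OrderField-class] for the frame.
#' @param lateralAxis,normalAxis axis indices (1 = x, 2 = y, 3 = z);
#'   the remaining axis is the thin one.
#' @param binWidth capillary width, nm; must yield at least
#'   `minCapillaries` capillaries.
#' @param nNormalBins number of bins of the normal-axis profile grid.
#' @param minMolecules capillaries with fewer molecules are flagged,
#'   excluded and logged.
#' @param minCapillaries minimum number of capillaries (default 8).
#' @return list with elements `profiles` (per-capillary data.frames with
#'   columns `y`, `o`), `x` (capillary centers, nm), `flagged` (logical),
#'   `shift` (normal shift applied, nm), `Lx`, `Lnormal`, `Lz`, `time`.
#' @export
binCapillaries <- function(frame, order, lateralAxis = 1L, normalAxis = 2L,
                           binWidth, nNormalBins = 40L, minMolecules = 20L,
                           minCapillaries = 8L) {
  stopifnot(is(frame, "Frame"), is(order, "OrderField"))
  box <- boxEdges(frame)
  thinAxis <- setdiff(1:3, c(lateralAxis, normalAxis))
  Lx <- box[lateralAxis]; Ln <- box[normalAxis]; Lz <- box[thinAxis]
  nCap <- floor(Lx / binWidth)
  if (nCap < minCapillaries)
    stop("binWidth gives only ", nCap, " capillaries (need >= ",
         minCapillaries, ")")
  xyz <- positions(frame)
  ov <- orderValues(order)
  keep <- !order@flagged & !is.na(ov)
  lat <- xyz[keep, lateralAxis]
  nrm <- xyz[keep, normalAxis]
  ov <- ov[keep]
  ## center the solid slab: circular mean of the normal coordinate
  ## weighted by the order value
  ang <- 2 * pi * nrm / Ln
  shift <- Ln * Arg(sum(ov * exp(complex(imaginary = ang)))) / (2 * pi) -
    Ln / 2
  nrm <- (nrm - shift) %% Ln
  capIdx <- pmin(floor(lat / binWidth) + 1L, nCap)
  yBreaks <- seq(0, Ln, length.out = nNormalBins + 1L)
  yMid <- (yBreaks[-1] + yBreaks[-length(yBreaks)]) / 2
  profiles <- vector("list", nCap)
  flagged <- logical(nCap)
  for (kc in seq_len(nCap)) {
    sel <- capIdx == kc
    if (sum(sel) < minMolecules) {
      flagged[kc] <- TRUE
      message("capillary ", kc, " has ", sum(sel),
              " molecules; flagged and excluded")
      next
    }
    bin <- findInterval(nrm[sel], yBreaks, rightmost.closed = TRUE)
    om <- tapply(ov[sel], factor(bin, levels = seq_len(nNormalBins)), mean)
    profiles[[kc]] <- data.frame(y = yMid, o = as.numeric(om))
  }
  list(profiles = profiles, x = (seq_len(nCap) - 0.5) * binWidth,
       flagged = flagged, shift = shift, Lx = nCap * binWidth, Lnormal = Ln,
       Lz = Lz, time = frameTime(frame))
}

.tanhSlab <- function(y, oS, oL, h1, h2, d1, d2)
  oL + (oS - oL) / 2 * (tanh((y - h1) / d1) - tanh((y - h2) / d2))

.tanhPrinted <- function(y, oS, oL, h1, h2, d1, d2)
  (oS + oL) / 2 + (oS - oL) / 2 * (tanh((y - h1) / d1) + tanh((y - h2) / d2))

#' Fit the two-interface tanh profile to a binned order-parameter profile
#'
#' Least-squares fit of the slab profile
#' `o(y) = oL + (oS - oL)/2 * [tanh((y - h1)/delta1) - tanh((y - h2)/delta2)]`,
#' which equals `oS` inside the solid slab and `oL` outside.  (The
#' additive-tanh variant that appears in parts of the CFM literature does
#' not reproduce the bulk levels in its asymptotic limits; it is available
#' as `form = "printed"` for comparison.)  Fitted parameters are
#' canonically ordered (`h1 < h2`, positive widths).
#'
#' @param profile data.frame with columns `y` (normal position, nm) and
#'   `o` (mean order parameter); NA rows are dropped.
#' @param form `"slab"` (default) or `"printed"`.
#' @param contrast minimum high-low range required to attempt a fit.
#' @param tol parameter convergence tolerance of the optimizer.
#' @return an [InterfaceProfileFit-class].
#' @export
fitTanhProfile <- function(profile, form = c("slab", "printed"),
                           contrast = 0.05, tol = 1e-8) {
  form <- match.arg(form)
  df <- profile[!is.na(profile$o), , drop = FALSE]
  if (nrow(df) < 8) stop("too few profile bins to fit two interfaces")
  rng <- range(df$o)
  if (diff(rng) < contrast)
    stop("no interface: profile contrast ", signif(diff(rng), 3),
         " below ", contrast)
  oL0 <- mean(df$o[df$o <= stats::quantile(df$o, 0.2)])
  oS0 <- mean(df$o[df$o >= stats::quantile(df$o, 0.8)])
  mid <- (oL0 + oS0) / 2
  high <- df$y[df$o >= mid]
  h10 <- min(high); h20 <- max(high)
  spacing <- stats::median(diff(sort(unique(df$y))))
  d0 <- max(spacing, (h20 - h10) / 10)
  dMin <- 0.1 * spacing    # keeps the Jacobian regular for sharp interfaces
  span <- diff(range(df$y))
  fitFun <- if (form == "slab") .tanhSlab else .tanhPrinted
  fit <- tryCatch(
    minpack.lm::nlsLM(
      o ~ fitFun(y, oS, oL, h1, h2, d1, d2), data = df,
      start = list(oS = oS0, oL = oL0, h1 = h10, h2 = h20, d1 = d0, d2 = d0),
      lower = c(oL0 - 1, oL0 - 1, min(df$y) - span, min(df$y) - span,
                dMin, dMin),
      upper = c(oS0 + 1, oS0 + 1, max(df$y) + span, max(df$y) + span,
                span, span),
      control = minpack.lm::nls.lm.control(
        ftol = tol^2, ptol = tol, maxiter = 500)),
    error = function(e) stop("tanh profile fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  if (cf[["h1"]] > cf[["h2"]])
    cf[c("h1", "h2", "d1", "d2")] <- cf[c("h2", "h1", "d2", "d1")]
  new("InterfaceProfileFit", oS = cf[["oS"]], oL = cf[["oL"]],
      h1 = cf[["h1"]], h2 = cf[["h2"]], delta1 = abs(cf[["d1"]]),
      delta2 = abs(cf[["d2"]]),
      residual = sqrt(sum(stats::resid(fit)^2)), form = form)
}

#' Assemble interface height fields from per-capillary profile fits
#'
#' Collects the two fitted interface positions of every capillary into two
#' height fields `h1(x)`, `h2(x)` and removes each field's mean (the zero
#' mode carries no capillary signal).  Frames where more than
#' `maxFailFraction` of capillaries failed are rejected.
#'
#' @param binned output of [binCapillaries()].
#' @param form,contrast passed to [fitTanhProfile()].
#' @param maxFailFraction maximum tolerated fraction of failed/flagged
#'   capillaries (default 0.2).
#' @return list of two [HeightField-class] objects (interface 1 and 2).
#' @export
buildHeightFields <- function(binned, form = "slab", contrast = 0.05,
                              maxFailFraction = 0.2) {
  nCap <- length(binned$profiles)
  h1 <- h2 <- rep(NA_real_, nCap)
  for (kc in seq_len(nCap)) {
    if (binned$flagged[kc] || is.null(binned$profiles[[kc]])) next
    fit <- tryCatch(fitTanhProfile(binned$profiles[[kc]], form = form,
                                   contrast = contrast),
                    error = function(e) NULL)
    if (!is.null(fit)) { h1[kc] <- fit@h1; h2[kc] <- fit@h2 }
  }
  bad <- sum(is.na(h1))
  if (bad / nCap > maxFailFraction)
    stop("frame dropped: ", bad, "/", nCap, " capillaries failed to fit")
  if (nCap - bad < 8) stop("fewer than 8 fitted capillaries")
  if (bad > 0) {   # interpolate isolated failures onto the uniform grid
    ok <- !is.na(h1)
    h1 <- stats::approx(binned$x[ok], h1[ok], xout = binned$x, rule = 2)$y
    h2 <- stats::approx(binned$x[ok], h2[ok], xout = binned$x, rule = 2)$y
  }
  list(new("HeightField", x = binned$x, h = h1 - mean(h1),
           time = binned$time),
       new("HeightField", x = binned$x, h = h2 - mean(h2),
           time = binned$time))
}

#' Extract the height fields of a synthetic capillary ensemble
#'
#' Each sample row of a [CapillaryEnsemble-class] is one interface height
#' field on the uniform lateral grid.
#'
#' @param ensemble a [CapillaryEnsemble-class].
#' @return list of [HeightField-class] objects.
#' @export
ensembleHeightFields <- function(ensemble) {
  stopifnot(is(ensemble, "CapillaryEnsemble"))
  lapply(seq_len(nrow(ensemble@heights)), function(i)
    new("HeightField", x = ensemble@x, h = ensemble@heights[i, ],
        time = as.numeric(i)))
}

#' Fluctuation power spectrum of interface height fields
#'
#' Averages `|h(q_n)|^2` over all supplied height fields with the forward
#' transform `h(q_n) = (1/M) sum_j h(x_j) exp(-i q_n x_j)` on the uniform
#' lateral grid (the convention under which the capillary equipartition
#' law holds with prefactor `kB*T/(Lx*Lz)`).  Each field's mean is removed
#' before transforming.
#'
#' @param fields list of [HeightField-class] objects on a common uniform
#'   grid (at least 2), or a [CapillaryEnsemble-class].
#' @param Lx lateral length, nm (inferred from an ensemble).
#' @param Lz interface thickness, nm (inferred from an ensemble).
#' @param nMax highest mode reported; default `floor((M - 1)/2)`, at most
#'   `M - 1`.
#' @return a [FluctuationSpectrum-class].
#' @examples
#' ens <- sampleCapillaryModes(4, 300, 20, 4, nSamples = 100, seed = 2)
#' sp <- powerSpectrum(ens)
#' @export
powerSpectrum <- function(fields, Lx = NULL, Lz = NULL, nMax = NULL) {
  if (is(fields, "CapillaryEnsemble")) {
    if (is.null(Lx)) Lx <- fields@Lx
    if (is.null(Lz)) Lz <- fields@Lz
    fields <- ensembleHeightFields(fields)
  }
  if (length(fields) < 2) stop("at least two height fields are required")
  if (is.null(Lx) || is.null(Lz)) stop("Lx and Lz are required")
  x <- fields[[1]]@x
  M <- length(x)
  dx <- diff(x)
  if (any(abs(dx - dx[1]) > 1e-9 * abs(dx[1])))
    stop("height-field grid must be uniform")
  if (is.null(nMax)) nMax <- floor((M - 1) / 2)
  nMax <- min(nMax, M - 1L)
  acc <- numeric(nMax)
  for (f in fields) {
    if (length(f@h) != M) stop("height fields must share one grid")
    hm <- f@h - mean(f@h)
    H <- stats::fft(hm) / M
    acc <- acc + Mod(H[2:(nMax + 1L)])^2
  }
  new("FluctuationSpectrum", q = 2 * pi * seq_len(nMax) / Lx,
      s2 = acc / length(fields), nFields = length(fields),
      Lx = Lx, Lz = Lz)
}

#' Fit the interfacial stiffness from a fluctuation spectrum
#'
#' Fits `ln <|h(q)|^2> = c - 2 ln q` (fixed slope -2) over a mode window
#' and inverts the equipartition relation:
#' `stiffness = kB * Tm / (Lx * Lz * exp(c))`.  The unconstrained log-log
#' slope over the same window is reported as a quality check; deviation
#' from -2 beyond `qcTolerance` records a warning in the estimate (not
#' fatal).  The default window starts at mode 2 (mode 1 is prone to drift
#' and finite-size effects) and extends while the cumulative unconstrained
#' slope stays within `qcTolerance` of -2.
#'
#' @param spectrum a [FluctuationSpectrum-class].
#' @param Tm melting temperature at which the fluctuations were sampled, K.
#' @param window integer mode indices to fit (>= 3 modes), or NULL for the
#'   automatic window.
#' @param qcTolerance allowed |slope + 2| (default 0.3).
#' @return a [StiffnessEstimate-class] with the stiffness in mJ/m^2.
#' @examples
#' ens <- sampleCapillaryModes(2.53, 150, 20, 4, nSamples = 500, seed = 11)
#' fitStiffness(powerSpectrum(ens), Tm = 150, window = 2:10)
#' @export
fitStiffness <- function(spectrum, Tm, window = NULL, qcTolerance = 0.3) {
  stopifnot(is(spectrum, "FluctuationSpectrum"))
  qSI <- toSI(spectrum@q, "nm^-1")
  sSI <- toSI(spectrum@s2, "nm^2")
  nModes <- length(qSI)
  if (is.null(window)) {
    window <- .autoWindow(log(qSI), log(sSI), qcTolerance)
  }
  window <- as.integer(window)
  if (length(window) < 3 || any(window < 1 | window > nModes))
    stop("fit window must contain >= 3 valid modes")
  if (any(sSI[window] <= 0))
    stop("non-positive spectral value inside the fit window")
  lq <- log(qSI[window]); ls <- log(sSI[window])
  cHat <- mean(ls + 2 * lq)
  resid <- ls + 2 * lq - cHat
  seC <- stats::sd(resid) / sqrt(length(window))
  qc <- stats::coef(stats::lm(ls ~ lq))[[2]]
  qcWarn <- abs(qc + 2) > qcTolerance
  if (qcWarn)
    warning(sprintf("unconstrained slope %.3f deviates from -2 beyond %.2f",
                    qc, qcTolerance))
  gSI <- kBoltzmann * Tm /
    (toSI(spectrum@Lx, "nm") * toSI(spectrum@Lz, "nm") * exp(cHat))
  new("StiffnessEstimate", stiffness = fromSI(gSI, "mJ/m^2"),
      se = fromSI(gSI, "mJ/m^2") * seC, window = window, intercept = cHat,
      qcSlope = qc, qcTolerance = qcTolerance, qcWarning = qcWarn)
}

.autoWindow <- function(lq, ls, tolerance) {
  nModes <- length(lq)
  if (nModes < 4) stop("too few modes for the automatic window")
  end <- 4L
  while (end <= nModes) {
    idx <- 2:end
    sl <- stats::coef(stats::lm(ls[idx] ~ lq[idx]))[[2]]
    if (abs(sl + 2) > tolerance) { end <- end - 1L; break }
    end <- end + 1L
  }
  2:min(end, nModes)
}

#' Estimate the stiffness from height fields with block-averaged errors
#'
#' Convenience wrapper: computes the averaged power spectrum of the fields
#' and runs the fixed-slope fit; the standard error is re-estimated by
#' splitting the fields into `nBlocks` blocks and taking the spread of the
#' per-block estimates.
#'
#' @param fields list of [HeightField-class] objects or a
#'   [CapillaryEnsemble-class].
#' @param Tm temperature, K.
#' @param Lx,Lz geometry, nm (inferred from an ensemble).
#' @param window,qcTolerance passed to [fitStiffness()].
#' @param nBlocks number of blocks for the error estimate.
#' @return a [StiffnessEstimate-class].
#' @export
estimateStiffness <- function(fields, Tm, Lx = NULL, Lz = NULL,
                              window = NULL, qcTolerance = 0.3,
                              nBlocks = 10L) {
  if (is(fields, "CapillaryEnsemble")) {
    Lx <- fields@Lx; Lz <- fields@Lz
    fields <- ensembleHeightFields(fields)
  }
  est <- fitStiffness(powerSpectrum(fields, Lx, Lz), Tm, window = window,
                      qcTolerance = qcTolerance)
  nF <- length(fields)
  if (nF >= 2 * nBlocks) {
    splitIdx <- split(seq_len(nF), cut(seq_len(nF), nBlocks, labels = FALSE))
    blockVals <- vapply(splitIdx, function(ii)
      suppressWarnings(stiffness(fitStiffness(
        powerSpectrum(fields[ii], Lx, Lz), Tm, window = est@window,
        qcTolerance = qcTolerance))), numeric(1))
    est@se <- stats::sd(blockVals) / sqrt(nBlocks)
  }
  est
}

#' Log-log plot of a fluctuation spectrum with the q^-2 guide line
#'
#' @param x a [FluctuationSpectrum-class].
#' @param y unused.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @aliases plot,FluctuationSpectrum,missing-method
#' @export
setMethod("plot", signature(x = "FluctuationSpectrum", y = "missing"),
  function(x, ...) {
    graphics::plot(x@q, x@s2, log = "xy", xlab = "q [1/nm]",
                   ylab = "<|h(q)|^2> [nm^2]", ...)
    ref <- x@s2[1] * (x@q / x@q[1])^(-2)
    graphics::lines(x@q, ref, lty = 2)
    invisible(x)
  })
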