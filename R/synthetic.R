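## Synthetic-data generators: every pipeline input with known ground truth.
## All generators take an explicit integer seed and leave the caller's RNG
## state untouched.

.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("an explicit integer seed is required")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Sample capillary interface height fields from the equipartition spectrum
#'
#' Draws an ensemble of quasi-one-dimensional interface height fields
#' `h(x)` whose Fourier modes obey the capillary equipartition law: mode
#' `n >= 1` is an independent zero-mean complex Gaussian with ensemble
#' variance `<|h(q_n)|^2> = kB*T / (Lx*Lz*stiffness*q_n^2)`,
#' `q_n = 2*pi*n/Lx`.  Fields are assembled directly in Fourier space and
#' inverse-transformed onto `M` uniform grid points `x_j = j*Lx/M`
#' (`j = 0..M-1`), with the convention `h(q_n) = (1/M) sum_j h(x_j)
#' exp(-i q_n x_j)` shared with [powerSpectrum()].  The zero mode is
#' excluded, so every sample has exactly zero mean.
#'
#' @param stiffness injected interfacial stiffness, mJ/m^2 (> 0).
#' @param temperature K.
#' @param Lx lateral length, nm.
#' @param Lz interface thickness, nm.
#' @param nModes number of populated modes (must stay below `nBins/2`).
#' @param nSamples ensemble size.
#' @param seed integer seed; identical seeds give identical ensembles.
#' @param nBins number of uniform grid points M.
#' @return a [CapillaryEnsemble-class].
#' @examples
#' ens <- sampleCapillaryModes(4, 300, 20, 4, nModes = 10,
#'                             nSamples = 200, seed = 7)
#' @export
sampleCapillaryModes <- function(stiffness, temperature, Lx, Lz,
                                 nModes = 10L, nSamples = 1000L, seed,
                                 nBins = 64L) {
  if (!is.finite(stiffness) || stiffness <= 0)
    stop("stiffness must be positive")
  if (temperature <= 0 || Lx <= 0 || Lz <= 0)
    stop("temperature and box dimensions must be positive")
  nModes <- as.integer(nModes); nBins <- as.integer(nBins)
  if (nModes >= nBins / 2)
    stop("nModes must be below the Nyquist mode nBins/2")
  vars <- capillaryModeVariance(stiffness, temperature, Lx, Lz,
                                seq_len(nModes))        # nm^2 per mode
  x <- (seq_len(nBins) - 1L) * Lx / nBins
  qn <- 2 * pi * seq_len(nModes) / Lx                   # nm^-1
  phase <- outer(qn, x)                                 # nModes x nBins
  cosM <- cos(phase); sinM <- sin(phase)
  heights <- .withSeed(seed, {
    sd <- sqrt(vars / 2)
    a <- matrix(stats::rnorm(nSamples * nModes), nSamples) %*% diag(sd, nModes)
    b <- matrix(stats::rnorm(nSamples * nModes), nSamples) %*% diag(sd, nModes)
    2 * (a %*% cosM - b %*% sinM)
  })
  new("CapillaryEnsemble", heights = heights, x = x, Lx = Lx, Lz = Lz,
      temperature = temperature, stiffness = stiffness, nModes = nModes,
      seed = as.integer(seed))
}

#' Equipartition variance of a capillary mode
#'
#' The target ensemble variance `kB*T / (Lx*Lz*stiffness*q_n^2)` in nm^2
#' for modes `n`, with `q_n = 2*pi*n/Lx`.
#'
#' @param stiffness mJ/m^2.
#' @param temperature K.
#' @param Lx,Lz nm.
#' @param n integer mode indices.
#' @return mode variances, nm^2.
#' @export
capillaryModeVariance <- function(stiffness, temperature, Lx, Lz, n) {
  qSI <- 2 * pi * n / toSI(Lx, "nm")
  sSI <- kBoltzmann * temperature /
    (toSI(Lx, "nm") * toSI(Lz, "nm") * toSI(stiffness, "mJ/m^2") * qSI^2)
  fromSI(sSI, "nm^2")
}

## FCC lattice positions for nx x ny x nz conventional cells of edge a,
## anchored at the origin; 4 molecules per cell.
.fccPositions <- function(cells, a) {
  basis <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
  g <- as.matrix(expand.grid(i = seq_len(cells[1]) - 1L,
                             j = seq_len(cells[2]) - 1L,
                             k = seq_len(cells[3]) - 1L))
  out <- matrix(NA_real_, 4 * nrow(g), 3)
  for (b in 1:4)
    out[seq.int(b, by = 4, length.out = nrow(g)), ] <-
      sweep(g, 2, basis[b, ], `+`)
  out * a
}

.chooseCells <- function(nCells, thinRatio, quasi1D) {
  ## default factorization: thin axis 1 cell, lateral ~ sqrt(nCells/2) so
  ## the normal axis gets about twice the lateral extent
  divs <- which(nCells %% seq_len(nCells) == 0)
  best <- NULL
  for (nx in divs) {
    ny <- nCells / nx
    if (ny < 1 || ny != round(ny)) next
    if (quasi1D && 1 > thinRatio * nx) next    # nz = 1 must satisfy aspect
    score <- abs(ny - 2 * nx)
    if (is.null(best) || score < best$score)
      best <- list(cells = c(nx, as.integer(ny), 1L), score = score)
  }
  if (is.null(best))
    stop("cannot factor ", nCells, " FCC cells into a quasi-1D slab; ",
         "pass geometry$cells explicitly")
  best$cells
}

#' Build a biphasic crystal/liquid configuration with ground-truth labels
#'
#' Constructs a periodic box holding an FCC crystal slab at density
#' `rhoCr` in the lower half of the normal axis (y) and a random liquid at
#' density `rhoLiq` in the upper half, separated by small gaps.  The
#' liquid is ideal-gas random with a minimum-separation rejection at
#' `0.7 x` the crystal nearest-neighbor distance — enough order-parameter
#' contrast for the downstream stages without modeling liquid structure.
#' Axis convention: x lateral (capillaries), y interface normal, z thin.
#'
#' @param nPerPhase molecules per phase; must equal `4*nx*ny*nz` for the
#'   FCC cell counts in use.
#' @param rhoCr crystal number density, nm^-3.
#' @param rhoLiq liquid number density, nm^-3.
#' @param geometry list with optional elements `cells` (integer
#'   `c(nx, ny, nz)`), `quasi1D` (enforce thin geometry, default TRUE),
#'   `thinRatio` (max Lz/Lx, default 0.2) and `gap` (phase gap in nm,
#'   default `0.3 * a`).
#' @param seed integer seed for the liquid placement.
#' @return a [Frame-class] with `labels` recording the ground truth
#'   (`"solid"` first, then `"liquid"`).
#' @examples
#' fr <- makeBiphasicConfiguration(500, rhoCr = 11.6, rhoLiq = 10.6, seed = 1)
#' table(moleculeLabels(fr))
#' @export
makeBiphasicConfiguration <- function(nPerPhase, rhoCr, rhoLiq,
                                      geometry = list(), seed) {
  if (rhoCr <= 0 || rhoLiq <= 0) stop("densities must be positive")
  quasi1D <- if (is.null(geometry$quasi1D)) TRUE else geometry$quasi1D
  thinRatio <- if (is.null(geometry$thinRatio)) 0.2 else geometry$thinRatio
  a <- (4 / rhoCr)^(1 / 3)                       # FCC lattice constant, nm
  if (nPerPhase %% 4 != 0)
    stop("nPerPhase must be a multiple of 4 (FCC filling count)")
  cells <- geometry$cells
  if (is.null(cells)) cells <- .chooseCells(nPerPhase / 4, thinRatio, quasi1D)
  cells <- as.integer(cells)
  if (4L * prod(cells) != as.integer(nPerPhase))
    stop("nPerPhase (", nPerPhase, ") is not 4*nx*ny*nz for cells ",
         paste(cells, collapse = "x"))
  Lx <- cells[1] * a; Lz <- cells[3] * a
  if (quasi1D && Lz / Lx > thinRatio + 1e-12)
    stop(sprintf("quasi-1D geometry violated: Lz/Lx = %.3f > %.3f",
                 Lz / Lx, thinRatio))
  gap <- if (is.null(geometry$gap)) 0.3 * a else geometry$gap
  crystal <- .fccPositions(cells, a)
  slabTop <- cells[2] * a
  liqLen <- nPerPhase / (rhoLiq * Lx * Lz)
  Ly <- slabTop + gap + liqLen + gap
  dnn <- a / sqrt(2)
  minSep <- 0.7 * dnn
  crystalEdge <- crystal[crystal[, 2] >= slabTop - minSep |
                           crystal[, 2] <= minSep, , drop = FALSE]
  liquid <- .withSeed(seed, {
    pts <- matrix(NA_real_, nPerPhase, 3)
    nPlaced <- 0L
    attempts <- 0L
    maxAttempts <- 400L * nPerPhase
    box <- c(Lx, Ly, Lz)
    while (nPlaced < nPerPhase) {
      attempts <- attempts + 1L
      if (attempts > maxAttempts)
        stop("liquid density too high for the minimum-separation tolerance")
      cand <- c(stats::runif(1, 0, Lx),
                stats::runif(1, slabTop + gap, slabTop + gap + liqLen),
                stats::runif(1, 0, Lz))
      ## reject overlaps against placed liquid AND the crystal slab (only
      ## its boundary layers can be within reach of the liquid region)
      other <- rbind(crystalEdge, pts[seq_len(nPlaced), , drop = FALSE])
      d <- minimumImage(other, matrix(cand, nrow(other), 3, byrow = TRUE),
                        box)
      if (min(rowSums(d^2)) < minSep^2) next
      nPlaced <- nPlaced + 1L
      pts[nPlaced, ] <- cand
    }
    pts
  })
  makeFrame(rbind(crystal, liquid), box = c(Lx, Ly, Lz),
            labels = rep(c("solid", "liquid"), each = nPerPhase))
}

#' Synthesize liquid and crystal thermodynamic branches
#'
#' Builds [ThermoCurves-class] with enthalpy branches linear in
#' temperature (constant heat capacities) and a melting discontinuity
#' `dHm` at `Tm`: `hCr(T) = hCrAtTm + cpCr*(T - Tm)` and
#' `hLiq(T) = hCrAtTm + dHm + cpLiq*(T - Tm)`, so
#' `hLiq(Tm) - hCr(Tm) = dHm` holds exactly.  Density laws are evaluated
#' on the grid (constants or functions of T).
#'
#' @param Tm melting temperature, K.
#' @param dHm melting enthalpy, J/molecule.
#' @param Tgrid temperature grid, K; points at or above `Tm` are dropped
#'   and `Tm` appended as the last grid point.  Must contain temperatures
#'   below `Tm`.
#' @param cpLiq,cpCr liquid/crystal heat capacities, J/K/molecule.  The
#'   defaults (5.5e-23 and 4.1e-23, about 4 kB and 3 kB) are free fixture
#'   parameters: the underlying study reports no heat capacities.
#' @param rhoLiq,rhoCr number-density laws, nm^-3: a constant or a
#'   function of T.  Defaults invert the per-molecule volumes 0.094 and
#'   0.086 nm^3 of demo system I.
#' @param hCrAtTm crystal enthalpy at `Tm`, J/molecule (zero reference).
#' @return a [ThermoCurves-class].
#' @examples
#' tc <- makeThermoCurves(Tm = 200, dHm = 1e-20, Tgrid = seq(100, 200, 5),
#'                        cpLiq = 4.1e-23, cpCr = 4.1e-23)
#' @export
makeThermoCurves <- function(Tm, dHm, Tgrid, cpLiq = 5.5e-23, cpCr = 4.1e-23,
                             rhoLiq = 1 / 0.094, rhoCr = 1 / 0.086,
                             hCrAtTm = 0) {
  if (dHm <= 0) stop("melting enthalpy must be positive")
  Tgrid <- sort(unique(as.numeric(Tgrid)))
  Tgrid <- c(Tgrid[Tgrid < Tm], Tm)
  if (length(Tgrid) < 2)
    stop("temperature grid must contain points below Tm ",
         "(driving force undefined on an above-Tm grid)")
  evalLaw <- function(law) {
    if (is.function(law)) vapply(Tgrid, law, numeric(1))
    else rep(as.numeric(law), length(Tgrid))
  }
  hCr <- hCrAtTm + cpCr * (Tgrid - Tm)
  hLiq <- hCrAtTm + dHm + cpLiq * (Tgrid - Tm)
  new("ThermoCurves", temperature = Tgrid, hLiq = hLiq, hCr = hCr,
      rhoLiq = evalLaw(rhoLiq), rhoCr = evalLaw(rhoCr), Tm = Tm, dHm = dHm)
}

#' Synthesize a per-molecule volume curve with an optional melting step
#'
#' Piecewise-linear per-molecule volume on a temperature grid with a
#' single step `vHigh - vLow` at `jumpAt` (the grid point at which the new
#' branch is first attained), emulating the volume discontinuity seen at a
#' first-order transition during heating.  With `jumpAt = NULL` a smooth
#' monotone baseline is produced (no transition to detect).
#'
#' @param Tgrid strictly increasing temperature grid, K.
#' @param vLow low-temperature branch volume at the step, nm^3.
#' @param vHigh high-temperature branch volume at the step, nm^3; must
#'   exceed `vLow` for a heating curve.
#' @param jumpAt step temperature, K; must lie inside the grid range.
#' @param slope thermal-expansion slope of both branches, nm^3/K.
#' @return a [TabularSeries-class] with column `V` (stored SI, declared
#'   nm^3).
#' @examples
#' v <- makeVolumeCurve(seq(10, 270, 5), vLow = 0.086, vHigh = 0.094,
#'                      jumpAt = 220)
#' @export
makeVolumeCurve <- function(Tgrid, vLow, vHigh = NULL, jumpAt = NULL,
                            slope = 1e-5) {
  Tgrid <- as.numeric(Tgrid)
  if (is.unsorted(Tgrid, strictly = TRUE))
    stop("Tgrid must be strictly increasing")
  if (is.null(jumpAt)) {
    v <- vLow + slope * (Tgrid - Tgrid[1])
  } else {
    if (jumpAt <= min(Tgrid) || jumpAt > max(Tgrid))
      stop("jumpAt must lie inside the temperature grid")
    if (is.null(vHigh) || vHigh <= vLow)
      stop("vHigh must exceed vLow for a heating curve")
    v <- ifelse(Tgrid < jumpAt, vLow + slope * (Tgrid - jumpAt),
                vHigh + slope * (Tgrid - jumpAt))
  }
  makeSeries(Tgrid, xUnit = "K", V = v, units = c(V = "nm^3"))
}

#' Generate a Brownian trajectory with known diffusion constant
#'
#' Isotropic Gaussian random walk: per-axis step variance `2*D*dt`, so the
#' Einstein relation gives `MSD(t) = 6*D*t` exactly in expectation.
#' Unwrapped coordinates are retained in every frame for MSD analysis;
#' wrapped coordinates live in a box sized to hold the walk.
#'
#' @param D diffusion constant, nm^2/ps (>= 0; 0 gives static particles).
#' @param nParticles number of particles.
#' @param nSteps number of steps (trajectory has `nSteps + 1` frames).
#' @param dt time step, ps (> 0).
#' @param seed integer seed.
#' @param box optional three box edges, nm; default sized from the
#'   expected excursion.
#' @return list of [Frame-class] objects at uniform time spacing.
#' @examples
#' trj <- makeBrownianTrajectory(0.001, nParticles = 10, nSteps = 50,
#'                               dt = 1, seed = 3)
#' @export
makeBrownianTrajectory <- function(D, nParticles, nSteps, dt, seed,
                                   box = NULL) {
  if (D < 0) stop("diffusion constant must be >= 0")
  if (dt <= 0) stop("time step must be positive")
  if (is.null(box)) {
    span <- max(1, 12 * sqrt(2 * D * dt * nSteps))
    box <- rep(span, 3)
  }
  .withSeed(seed, {
    start <- matrix(stats::runif(nParticles * 3), ncol = 3) %*% diag(box)
    sdStep <- sqrt(2 * D * dt)
    frames <- vector("list", nSteps + 1L)
    cur <- start
    frames[[1]] <- makeFrame(cur, box = box, time = 0, unwrapped = cur)
    for (s in seq_len(nSteps)) {
      cur <- cur + matrix(stats::rnorm(nParticles * 3, sd = sdStep), ncol = 3)
      frames[[s + 1L]] <- makeFrame(cur, box = box, time = s * dt,
                                    unwrapped = cur)
    }
    frames
  })
}

#' Generate a VFT-shaped diffusion series
#'
#' Evaluates `log10(1/D) = log10(1/D0) + log10(e)*B/(T - T0)` on a
#' temperature grid and adds Gaussian noise of `noiseDex` decades in
#' log10 units.  All grid temperatures must exceed `T0`.
#'
#' @param D0 high-temperature limit of D, m^2/s.
#' @param B activation parameter, K.
#' @param T0 Vogel temperature, K.
#' @param Tgrid temperature grid, K (all `> T0`).
#' @param noiseDex noise standard deviation in log10 units (0 = exact).
#' @param seed integer seed (only used when `noiseDex > 0`).
#' @return a [TabularSeries-class] with column `D` in m^2/s.
#' @examples
#' d <- makeVFTDiffusion(10^10.68 * 1e-21, 520, 35, seq(140, 220, 10))
#' @export
makeVFTDiffusion <- function(D0, B, T0, Tgrid, noiseDex = 0, seed = 1L) {
  if (any(Tgrid <= T0))
    stop("all grid temperatures must exceed T0 (VFT undefined at/below it)")
  log10invD <- log10(1 / D0) + log10(exp(1)) * B / (Tgrid - T0)
  if (noiseDex > 0)
    log10invD <- .withSeed(seed, log10invD +
                             stats::rnorm(length(Tgrid), sd = noiseDex))
  makeSeries(Tgrid, xUnit = "K", D = 10^(-log10invD), units = c(D = "m^2/s"))
}
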