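## Fixture builders shared across the suite.  Everything is generated in
## code; no stored data files.

## the 12 ideal FCC first-shell directions (units of d_nn)
fccShellDirections <- function() {
  d <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0),
             c(1, 0, 1), c(1, 0, -1), c(-1, 0, 1), c(-1, 0, -1),
             c(0, 1, 1), c(0, 1, -1), c(0, -1, 1), c(0, -1, -1))
  d / sqrt(2)
}

## periodic FCC frame of nCells^3 conventional cells, lattice constant a
fccFrame <- function(nCells = 4L, a = 0.72, jitter = 0, seed = 1L) {
  basis <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
  g <- as.matrix(expand.grid(0:(nCells - 1), 0:(nCells - 1),
                             0:(nCells - 1)))
  pos <- do.call(rbind, lapply(1:4, function(b) sweep(g, 2, basis[b, ], `+`)))
  pos <- pos * a
  if (jitter > 0) {
    set.seed(seed)
    pos <- pos + matrix(rnorm(length(pos), sd = jitter), ncol = 3)
  }
  makeFrame(pos, box = rep(nCells * a, 3))
}

## random rotation matrix (Haar via QR, det +1)
randomRotation <- function(seed) {
  set.seed(seed)
  qr <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr) %*% diag(sign(diag(qr.R(qr))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

## independent direct-sum Steinhardt oracle on explicit bond directions
## (no neighbor machinery; used to cross-check steinhardtQ)
steinhardtOracle <- function(dirs, l) {
  th <- acos(pmin(1, pmax(-1, dirs[, 3] / sqrt(rowSums(dirs^2)))))
  ph <- atan2(dirs[, 2], dirs[, 1])
  qlm <- colMeans(sphericalHarmonics(l, th, ph))
  sqrt(4 * pi / (2 * l + 1) * sum(Mod(qlm)^2))
}

## noiseless analytic equipartition spectrum as a FluctuationSpectrum
analyticSpectrum <- function(stiffness, Tm, Lx, Lz, nModes = 10L) {
  FluctuationSpectrum(
    q = 2 * pi * seq_len(nModes) / Lx,
    s2 = capillaryModeVariance(stiffness, Tm, Lx, Lz, seq_len(nModes)),
    nFields = 1L, Lx = Lx, Lz = Lz)
}

## standard quasi-1D biphasic fixture used in several tests
biphasicFixture <- function(seed = 11L, nPerPhase = 864L) {
  makeBiphasicConfiguration(nPerPhase, rhoCr = 1 / 0.086,
                            rhoLiq = 1 / 0.094, seed = seed)
}
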