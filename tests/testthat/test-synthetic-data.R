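test_that("capillary ensemble reproduces the equipartition mode variances", {
  ens <- sampleCapillaryModes(4, 300, 20, 4, nModes = 10, nSamples = 2000,
                              seed = 42)
  sp <- powerSpectrum(ens)
  target1 <- capillaryModeVariance(4, 300, 20, 4, 1)
  ## direct evaluation of kB*T/(Lx*Lz*stiffness*q1^2)
  q1 <- 2 * pi / 20e-9
  expect_equal(target1,
               1.380649e-23 * 300 / (20e-9 * 4e-9 * 4e-3 * q1^2) / 1e-18,
               tolerance = 1e-12)
  ## empirical mode-1 variance within 5% at 2000 samples
  expect_lt(abs(spectrumValues(sp)[1] - target1) / target1, 0.05)
  ## q^-2 law: target variance of mode 2 is exactly 1/4 of mode 1
  expect_equal(capillaryModeVariance(4, 300, 20, 4, 2), target1 / 4,
               tolerance = 1e-12)
  ## determinism and zero-mean samples
  ens2 <- sampleCapillaryModes(4, 300, 20, 4, nModes = 10, nSamples = 2000,
                               seed = 42)
  expect_identical(ens@heights, ens2@heights)
  expect_lt(max(abs(rowMeans(ens@heights))), 1e-12)
  expect_error(sampleCapillaryModes(-1, 300, 20, 4, seed = 1), "positive")
})

test_that("biphasic configuration has the advertised structure and labels", {
  fr <- makeBiphasicConfiguration(500, rhoCr = 11.6, rhoLiq = 10.6, seed = 1)
  expect_equal(nMolecules(fr), 1000L)
  expect_equal(sum(moleculeLabels(fr) == "solid"), 500L)
  ## quasi-1D thin axis
  box <- boxEdges(fr)
  expect_lte(box[3] / box[1], 0.2 + 1e-12)
  ## interior crystal molecules have the full FCC coordination of 12
  ## within 1.1x the nearest-neighbor distance (thicker non-quasi-1D box
  ## so the cutoff is valid)
  fr2 <- makeBiphasicConfiguration(432, rhoCr = 1 / 0.086,
                                   rhoLiq = 1 / 0.094,
                                   geometry = list(cells = c(6L, 9L, 2L),
                                                   quasi1D = FALSE),
                                   seed = 4)
  a <- (4 * 0.086)^(1 / 3)
  nb <- findNeighbors(fr2, cutoff = 1.1 * a / sqrt(2))
  xyz <- positions(fr2)
  interior <- which(moleculeLabels(fr2) == "solid" &
                    xyz[, 2] > 1.5 * a & xyz[, 2] < 7.5 * a)
  expect_true(length(interior) > 100)
  expect_true(all(lengths(nb@idx[interior]) == 12L))
  ## liquid honors the minimum separation
  liq <- which(moleculeLabels(fr2) == "liquid")
  nbl <- findNeighbors(fr2, k = 1)
  dmin <- min(vapply(liq, function(i)
    sqrt(sum(neighborDisplacements(nbl, i)[1, ]^2)), numeric(1)))
  expect_gt(dmin, 0.7 * a / sqrt(2) - 1e-9)
  ## invalid inputs
  expect_error(makeBiphasicConfiguration(503, 11.6, 10.6, seed = 1),
               "multiple of 4")
})

test_that("thermo curves honor the melting boundary construction", {
  ## equal slopes: constant enthalpy gap everywhere
  tc <- makeThermoCurves(Tm = 200, dHm = 1e-20, Tgrid = seq(100, 200, 5),
                         cpLiq = 4.1e-23, cpCr = 4.1e-23)
  expect_equal(tc@hLiq - tc@hCr, rep(1e-20, length(tc@temperature)),
               tolerance = 1e-12)
  ## exact boundary identity for unequal slopes too
  tc2 <- makeThermoCurves(Tm = 200, dHm = 1e-20, Tgrid = seq(100, 200, 5))
  n <- length(tc2@temperature)
  expect_identical(tc2@hLiq[n] - tc2@hCr[n], 1e-20)
  ## grid entirely above Tm is rejected
  expect_error(makeThermoCurves(Tm = 200, dHm = 1e-20,
                                Tgrid = seq(210, 250, 5)), "below Tm")
})

test_that("volume curves carry a single step of the requested size", {
  v <- makeVolumeCurve(seq(10, 270, 5), vLow = 0.086, vHigh = 0.094,
                       jumpAt = 220)
  vv <- fromSI(seriesColumn(v, "V"), "nm^3")
  Tg <- fromSI(seriesX(v), "K")
  steps <- diff(vv)
  expect_equal(Tg[which.max(steps) + 1], 220)
  expect_gt(max(steps), 0.008)          # step plus one grid-interval slope
  expect_error(makeVolumeCurve(seq(10, 270, 5), vLow = 0.094,
                               vHigh = 0.086, jumpAt = 220), "exceed")
  expect_error(makeVolumeCurve(seq(10, 270, 5), vLow = 0.086,
                               vHigh = 0.094, jumpAt = 500), "inside")
})

test_that("Brownian generator: static limit, reproducibility, unwrapped", {
  trj0 <- makeBrownianTrajectory(0, nParticles = 5, nSteps = 20, dt = 1,
                                 seed = 2)
  m0 <- msd(trj0)
  expect_equal(max(abs(seriesColumn(m0, "MSD"))), 0)
  trjA <- makeBrownianTrajectory(0.01, 5, 20, dt = 1, seed = 7)
  trjB <- makeBrownianTrajectory(0.01, 5, 20, dt = 1, seed = 7)
  expect_identical(unwrappedPositions(trjA[[21]]),
                   unwrappedPositions(trjB[[21]]))
  expect_error(makeBrownianTrajectory(0.01, 5, 20, dt = 0, seed = 1),
               "positive")
  expect_error(makeBrownianTrajectory(-1, 5, 20, dt = 1, seed = 1), ">= 0")
})

test_that("VFT generator matches the closed form and is reproducible", {
  ## noiseless system-I demo parameters
  Tg <- seq(140, 220, 10)
  d <- makeVFTDiffusion(10^10.68, 520, 35, Tg)
  got <- -log10(seriesColumn(d, "D"))
  expect_equal(got, -10.68 + log10(exp(1)) * 520 / (Tg - 35),
               tolerance = 1e-12)
  ## asymptote: at very large T, log10(1/D) -> log10(1/D0)
  dInf <- makeVFTDiffusion(1e-10, 520, 35, 1e9)
  expect_equal(-log10(seriesColumn(dInf, "D")), 10, tolerance = 1e-6)
  ## seeded noise reproducibility
  dn1 <- makeVFTDiffusion(1e-10, 520, 35, Tg, noiseDex = 0.05, seed = 3)
  dn2 <- makeVFTDiffusion(1e-10, 520, 35, Tg, noiseDex = 0.05, seed = 3)
  expect_identical(seriesColumn(dn1, "D"), seriesColumn(dn2, "D"))
  expect_error(makeVFTDiffusion(1e-10, 520, 35, seq(20, 100, 10)), "T0")
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(123); before <- .Random.seed
  invisible(sampleCapillaryModes(4, 300, 20, 4, nSamples = 10, seed = 9))
  invisible(makeBrownianTrajectory(0.01, 3, 5, dt = 1, seed = 9))
  expect_identical(.Random.seed, before)
})
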