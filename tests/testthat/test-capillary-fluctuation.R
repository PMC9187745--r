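test_that("capillary binning produces per-bin profiles spanning both phases", {
  fr <- biphasicFixture(seed = 11)
  of <- steinhardtQ(fr, findNeighbors(fr, k = 12))
  Lx <- boxEdges(fr)[1]
  bc <- binCapillaries(fr, of, binWidth = Lx / 9, nNormalBins = 36)
  expect_length(bc$profiles, 9L)
  expect_false(any(bc$flagged))
  ## each capillary profile reaches both bulk levels
  for (p in bc$profiles) {
    o <- p$o[!is.na(p$o)]
    expect_gt(max(o), 0.25)
    expect_lt(min(o), 0.15)
  }
  ## too coarse a binWidth is rejected
  expect_error(binCapillaries(fr, of, binWidth = Lx / 3), "capillaries")
  ## sparse capillaries are flagged, not fatal
  small <- makeFrame(matrix(runif(30 * 3, 0, 2), ncol = 3) %*%
                       diag(c(8, 2, 2)), box = c(16, 4, 4))
  ofs <- steinhardtQ(small, findNeighbors(small, k = 3))
  expect_message(bcs <- binCapillaries(small, ofs, binWidth = 2,
                                       minMolecules = 20),
                 "flagged")
  expect_true(any(bcs$flagged))
})

test_that("tanh profile fit recovers noiseless and noisy parameters", {
  y <- seq(0.5, 39.5, 1)
  truth <- list(oS = 0.40, oL = 0.05, h1 = 10, h2 = 30, d = 1)
  o <- truth$oL + (truth$oS - truth$oL) / 2 *
    (tanh((y - truth$h1) / truth$d) - tanh((y - truth$h2) / truth$d))
  fit <- fitTanhProfile(data.frame(y = y, o = o))
  expect_equal(c(fit@oS, fit@oL, fit@h1, fit@h2, fit@delta1, fit@delta2),
               c(0.40, 0.05, 10, 30, 1, 1), tolerance = 1e-6)
  ## Gaussian noise sigma = 0.01: repeated-fit study recovers the
  ## interface positions within 0.1 nm on average
  set.seed(21)
  errs <- t(vapply(1:6, function(rep) {
    fitN <- fitTanhProfile(data.frame(y = y,
                                      o = o + rnorm(length(y), 0, 0.01)))
    c(abs(fitN@h1 - 10), abs(fitN@h2 - 30))
  }, numeric(2)))
  expect_lt(mean(errs[, 1]), 0.1)
  expect_lt(mean(errs[, 2]), 0.1)
  expect_lt(max(errs), 0.3)
  ## flat profile: no interface
  expect_error(fitTanhProfile(data.frame(y = y, o = rep(0.2, length(y)))),
               "no interface")
  ## printed (additive-tanh) form is selectable and fits its own curve
  oP <- (0.40 + 0.05) / 2 + (0.40 - 0.05) / 2 *
    (tanh((y - 10) / 1) + tanh((y - 30) / 1))
  fitP <- fitTanhProfile(data.frame(y = y, o = oP), form = "printed")
  expect_equal(c(fitP@h1, fitP@h2), c(10, 30), tolerance = 1e-5)
})

test_that("height fields recover an injected sine displacement", {
  ## build analytic capillary profiles: interface 1 displaced by a sine,
  ## interface 2 planar
  xk <- (seq_len(10) - 0.5) * 2                    # 10 capillaries, Lx = 20
  yg <- seq(0.5, 39.5, 1)
  A <- 0.5; q1 <- 2 * pi / 20
  profiles <- lapply(seq_along(xk), function(k) {
    h1 <- 10 + A * cos(q1 * xk[k])
    o <- 0.05 + 0.35 / 2 * (tanh((yg - h1) / 1) - tanh((yg - 30) / 1))
    data.frame(y = yg, o = o)
  })
  binned <- list(profiles = profiles, x = xk, flagged = rep(FALSE, 10),
                 shift = 0, Lx = 20, Lnormal = 40, Lz = 4, time = 0)
  hf <- buildHeightFields(binned)
  expect_equal(hf[[1]]@h, A * cos(q1 * xk) - mean(A * cos(q1 * xk)),
               tolerance = 1e-4)
  expect_lt(max(abs(hf[[2]]@h)), 1e-4)             # planar after mean removal
  ## spectrum of the sine field: |h(q1)|^2 = A^2/4, other modes ~ 0
  sp <- powerSpectrum(list(hf[[1]], hf[[1]]), Lx = 20, Lz = 4)
  expect_equal(spectrumValues(sp)[1], A^2 / 4, tolerance = 1e-6)
  expect_lt(max(spectrumValues(sp)[-1]), 1e-10)
  ## dropping more than 20% of capillaries rejects the frame
  binned$flagged[1:3] <- TRUE
  expect_error(buildHeightFields(binned), "dropped")
})

test_that("power spectrum satisfies Parseval and rejects bad grids", {
  set.seed(31)
  h <- rnorm(64)
  fld <- HeightField(x = (0:63) * 20 / 64, h = h, time = 0)
  sp <- powerSpectrum(list(fld, fld), Lx = 20, Lz = 4, nMax = 63)
  hm <- h - mean(h)
  expect_equal(sum(spectrumValues(sp)), mean(hm^2), tolerance = 1e-10)
  ## zero fields give an identically zero spectrum
  z <- HeightField(x = (0:63) * 20 / 64, h = rep(0, 64), time = 0)
  expect_equal(max(spectrumValues(powerSpectrum(list(z, z), 20, 4))), 0)
  bad <- HeightField(x = c(0, 1, 3, 7), h = rnorm(4), time = 0)
  expect_error(powerSpectrum(list(bad, bad), 20, 4), "uniform")
  expect_error(powerSpectrum(list(z), 20, 4), "two height fields")
})

test_that("stiffness fit inverts the analytic spectrum exactly", {
  sp <- analyticSpectrum(4, 300, 20, 4, nModes = 10)
  est <- fitStiffness(sp, Tm = 300, window = 2:10)
  expect_equal(stiffness(est), 4, tolerance = 1e-10)
  expect_equal(qcSlope(est), -2, tolerance = 1e-9)
  expect_false(est@qcWarning)
  ## windows below 3 modes are rejected
  expect_error(fitStiffness(sp, Tm = 300, window = 2:3), ">= 3")
  ## white-noise spectrum: QC slope near 0, warning recorded
  wn <- FluctuationSpectrum(q = 2 * pi * (1:10) / 20, s2 = rep(0.01, 10),
                            nFields = 2L, Lx = 20, Lz = 4)
  expect_warning(estW <- fitStiffness(wn, Tm = 300, window = 2:10),
                 "slope")
  expect_lt(abs(qcSlope(estW)), 0.2)
  expect_true(estW@qcWarning)
})

test_that("end-to-end CFM recovery across stiffness values", {
  ## 2000 samples: within 10% for each injected stiffness
  for (g in c(1, 2.53, 4.15, 8)) {
    ens <- sampleCapillaryModes(g, 150, 20, 4, nModes = 10,
                                nSamples = 2000, seed = 1000 + round(100 * g))
    est <- fitStiffness(powerSpectrum(ens), Tm = 150, window = 2:10)
    expect_lt(abs(stiffness(est) - g) / g, 0.10)
  }
  ## 20000 samples: within 3%
  ens <- sampleCapillaryModes(2.53, 150, 20, 4, nModes = 10,
                              nSamples = 20000, seed = 77)
  est <- fitStiffness(powerSpectrum(ens), Tm = 150, window = 2:10)
  expect_lt(abs(stiffness(est) - 2.53) / 2.53, 0.03)
  ## block-averaged standard error is reported and positive
  estB <- estimateStiffness(ens, Tm = 150, window = 2:10)
  expect_gt(stiffnessSE(estB), 0)
})

test_that("stiffness estimate is invariant under interface relabeling", {
  ens <- sampleCapillaryModes(2.53, 150, 20, 4, nModes = 10,
                              nSamples = 400, seed = 5)
  flds <- ensembleHeightFields(ens)
  a <- fitStiffness(powerSpectrum(flds, 20, 4), 150, window = 2:10)
  b <- fitStiffness(powerSpectrum(rev(flds), 20, 4), 150, window = 2:10)
  expect_equal(stiffness(a), stiffness(b), tolerance = 1e-12)
})

test_that("particle-level CFM pipeline yields height fields on the fixture", {
  fr <- biphasicFixture(seed = 11)
  of <- steinhardtQ(fr, findNeighbors(fr, k = 12))
  bc <- binCapillaries(fr, of, binWidth = boxEdges(fr)[1] / 9,
                       nNormalBins = 36)
  hf <- buildHeightFields(bc)
  expect_length(hf, 2L)
  ## mean removed
  expect_lt(abs(mean(hf[[1]]@h)), 1e-12)
  expect_lt(abs(mean(hf[[2]]@h)), 1e-12)
  ## static lattice-vs-liquid interfaces are nearly planar: fitted
  ## roughness stays below the capillary bin width
  expect_lt(sd(hf[[1]]@h), 1)
})
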