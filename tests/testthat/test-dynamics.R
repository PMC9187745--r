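test_that("MSD handles static, ballistic and translated trajectories", {
  ## static
  trj0 <- makeBrownianTrajectory(0, 5, 30, dt = 1, seed = 2)
  expect_equal(max(abs(seriesColumn(msd(trj0), "MSD"))), 0)
  ## ballistic r = v t with v = 0.1 nm/ps: MSD(t) = 0.01 t^2
  mk <- function(offset = c(0, 0, 0)) lapply(0:20, function(t) {
    p <- matrix(c(1 + 0.1 * t, 1, 1) + offset, ncol = 3)
    makeFrame(p, box = c(100, 100, 100), time = t, unwrapped = p)
  })
  mb <- msd(mk(), maxLag = 10)
  lag <- fromSI(seriesX(mb), "ps")
  expect_equal(fromSI(seriesColumn(mb, "MSD"), "nm^2"), 0.01 * lag^2,
               tolerance = 1e-10)
  ## invariance under global translation
  mb2 <- msd(mk(offset = c(17, -4, 9)), maxLag = 10)
  expect_equal(seriesColumn(mb2, "MSD"), seriesColumn(mb, "MSD"),
               tolerance = 1e-10)
  ## non-uniform sampling rejected
  bad <- mk()
  bad[[3]]@time <- 7
  expect_error(msd(bad), "uniform")
})

test_that("Brownian fixture diffusion is recovered via the Einstein relation", {
  trj <- makeBrownianTrajectory(0.001, nParticles = 200, nSteps = 2000,
                                dt = 1, seed = 9)
  m <- msd(trj, maxLag = 400)
  res <- diffusionFromMsd(m, fitWindow = c(50, 400))
  expect_lt(abs(fromSI(res$D, "nm^2/ps") - 0.001) / 0.001, 0.05)
  expect_false(res$qcWarning)
  expect_lt(abs(res$qcSlope - 1), 0.1)
})

test_that("diffusionFromMsd inverts exact lines and flags ballistic input", {
  ## exact MSD = 6 D t with D = 1e-10 m^2/s = 1e-4 nm^2/ps
  t <- 1:100
  m <- makeSeries(t, xUnit = "ps", MSD = 6 * 1e-4 * t,
                  units = c(MSD = "nm^2"))
  res <- diffusionFromMsd(m, fitWindow = c(10, 100))
  expect_equal(res$D, 1e-10, tolerance = 1e-10)
  ## ballistic input: QC log-log slope 2, warning
  mb <- makeSeries(t, xUnit = "ps", MSD = 0.01 * t^2, units = c(MSD = "nm^2"))
  expect_warning(resB <- diffusionFromMsd(mb, fitWindow = c(10, 100)),
                 "not diffusive")
  expect_equal(resB$qcSlope, 2, tolerance = 1e-6)
  expect_true(resB$qcWarning)
})

test_that("VFT fit recovers the demo parameter sets from noiseless data", {
  cases <- list(c(-10.68, 520, 35), c(-11.10, 1200, 17))
  for (p in cases) {
    Tg <- seq(140, 260, 10)
    if (p[3] < 30) Tg <- seq(120, 260, 10)
    d <- makeVFTDiffusion(10^(-p[1]), p[2], p[3], Tg)
    fit <- fitVFT(d)
    expect_equal(fit@log10invD0, p[1], tolerance = 5e-4)
    expect_equal(fit@B, p[2], tolerance = 5e-4)
    expect_equal(fit@T0, p[3], tolerance = 5e-4)
    ## round trip: eval on fitted params reproduces the input
    expect_equal(evalVFT(fit, Tg), seriesColumn(d, "D"), tolerance = 1e-9)
  }
})

test_that("VFT fit is exact on noiseless data across random parameters", {
  set.seed(99)
  for (i in 1:8) {
    p <- c(runif(1, -12, 12), runif(1, 100, 2000), runif(1, 0, 120))
    Tg <- seq(p[3] + 50, p[3] + 350, length.out = 12)
    d <- makeVFTDiffusion(10^(-p[1]), p[2], p[3], Tg)
    fit <- fitVFT(d)
    expect_equal(c(fit@log10invD0, fit@B, fit@T0), p, tolerance = 1e-3)
  }
})

test_that("VFT degenerate and invalid cases behave", {
  ## Arrhenius data (T0 = 0): fitted T0 within 2 K of 0
  Tg <- seq(100, 400, 20)
  d <- makeVFTDiffusion(1e-9, 800, 0, Tg)
  fit <- fitVFT(d)
  expect_lt(fit@T0, 2)
  ## evaluation below T0 is a domain error
  vp <- VFTParams(log10invD0 = 10, B = 500, T0 = 50)
  expect_error(evalVFT(vp, 40), "T0")
  ## asymptote: D -> D0 as T -> infinity
  expect_equal(log10(1 / evalVFT(vp, 1e9)), 10, tolerance = 1e-6)
  ## insufficient spread rejected
  dn <- makeVFTDiffusion(1e-9, 800, 0, seq(100, 110, 2))
  expect_error(fitVFT(dn), "spread")
})
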