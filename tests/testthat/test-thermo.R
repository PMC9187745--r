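test_that("entropy difference matches closed forms", {
  ## constant gap (equal heat capacities): dS = dSm = dHm/Tm everywhere
  tc <- makeThermoCurves(Tm = 200, dHm = 1e-20, Tgrid = seq(100, 200, 1),
                         cpLiq = 4.1e-23, cpCr = 4.1e-23)
  ds <- seriesColumn(deltaEntropy(tc), "dS")
  expect_equal(ds, rep(5e-23, length(ds)), tolerance = 1e-10)
  ## linear gap with slope c: dS(T) = dSm + c*ln(T/Tm), 1e-4 relative on a
  ## 1 K grid, checked at three temperatures
  c0 <- 2e-23
  tc2 <- makeThermoCurves(Tm = 200, dHm = 1e-20, Tgrid = seq(100, 200, 1),
                          cpLiq = 4.1e-23 + c0, cpCr = 4.1e-23)
  ds2 <- deltaEntropy(tc2)
  Tg <- fromSI(seriesX(ds2), "K")
  got <- seriesColumn(ds2, "dS")
  want <- 1e-20 / 200 + c0 * log(Tg / 200)
  for (Tq in c(120, 150, 180)) {
    i <- which(Tg == Tq)
    expect_equal(got[i], want[i], tolerance = 1e-4)
  }
  ## T = 0 in the grid is rejected
  tc0 <- tc
  expect_error({
    bad <- makeThermoCurves(Tm = 200, dHm = 1e-20, Tgrid = c(0, 100, 200))
    deltaEntropy(bad)
  }, "positive")
})

test_that("driving force integrates from Tm with the exact boundary zero", {
  tc <- makeThermoCurves(Tm = 200, dHm = 1e-20, Tgrid = seq(100, 200, 1),
                         cpLiq = 4.1e-23, cpCr = 4.1e-23)
  df <- drivingForceFromCurves(tc)
  n <- length(df@temperature)
  expect_identical(df@dG[n], 0)
  ## constant dS: dG(T) = dSm*(Tm - T); at 180 K with dHm=1e-20, Tm=200:
  i <- which(df@temperature == 180)
  expect_equal(df@dG[i], 1e-21, tolerance = 1e-12)
  ## monotone: dG decreases with increasing T below Tm when dS > 0
  expect_true(all(diff(df@dG) < 0))
  ## trapezoid is exact on linear integrands: halving the grid changes
  ## dG(180) by < 1e-6 relative
  tcF <- makeThermoCurves(Tm = 200, dHm = 1e-20, Tgrid = seq(100, 200, 0.5),
                          cpLiq = 4.1e-23, cpCr = 4.1e-23)
  dfF <- drivingForceFromCurves(tcF)
  iF <- which(dfF@temperature == 180)
  expect_equal(dfF@dG[iF], df@dG[i], tolerance = 1e-6)
  ## volumetric conversion: dGv = dG * rhoCr in SI, to 1e-12 relative
  expect_equal(df@dGv, df@dG * toSI(tc@rhoCr, "nm^-3"), tolerance = 1e-12)
})

test_that("Turnbull scaling obeys its boundary and scaling identities", {
  Tg <- seq(100, 200, 5)
  tc <- makeThermoCurves(Tm = 200, dHm = 1e-20, Tgrid = Tg,
                         cpLiq = 4.1e-23, cpCr = 4.1e-23)
  g <- turnbullGamma(2.53, tc)
  ## constant rho and dH: gamma(T) = gammaM everywhere
  expect_equal(g@gamma, rep(2.53, length(g@temperature)), tolerance = 1e-12)
  expect_equal(g@gamma[length(g@gamma)], 2.53)
  ## density ratio 8 with constant dH scales gamma by 8^(2/3) = 4
  tc8 <- makeThermoCurves(Tm = 200, dHm = 1e-20, Tgrid = Tg,
                          cpLiq = 4.1e-23, cpCr = 4.1e-23,
                          rhoCr = function(T) if (T < 200) 8 * 11.6 else 11.6)
  g8 <- turnbullGamma(1, tc8)
  expect_equal(g8@gamma[1], 4, tolerance = 1e-12)
  ## non-positive enthalpy gap is unphysical below melting
  tcBad <- tc
  tcBad@hLiq[1] <- tcBad@hCr[1] - 1e-21
  expect_error(turnbullGamma(2.53, tcBad), "non-positive")
  expect_error(turnbullGamma(-1, tc), "positive")
})

test_that("transition detector finds the largest qualifying volume step", {
  v <- makeVolumeCurve(seq(10, 270, 5), vLow = 0.086, vHigh = 0.094,
                       jumpAt = 220)
  tr <- detectTransition(v, minJump = 0.004)
  expect_equal(tr$temperature, 220)
  expect_equal(tr$jump, 0.008, tolerance = 0.01)
  ## smooth monotone curve: nothing to detect
  v0 <- makeVolumeCurve(seq(10, 270, 5), vLow = 0.086)
  expect_null(detectTransition(v0, minJump = 0.004))
  ## two steps: the larger one wins
  Tg <- seq(100, 300, 5)
  vv <- ifelse(Tg < 150, 0.080, ifelse(Tg < 250, 0.084, 0.097))
  v2 <- makeSeries(Tg, xUnit = "K", V = vv, units = c(V = "nm^3"))
  tr2 <- detectTransition(v2, minJump = 0.003)
  expect_equal(tr2$temperature, 250)
  expect_equal(tr2$jump, 0.013, tolerance = 1e-9)
})
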