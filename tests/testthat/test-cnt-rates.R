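test_that("nucleation barrier follows (16/3) gamma^3 / dGv^2", {
  expect_equal(nucleationBarrier(1, 1), 16 / 3, tolerance = 1e-15)
  ## direct arithmetic at physical values
  expect_equal(nucleationBarrier(2.53e-3, 1e6),
               (16 / 3) * (2.53e-3)^3 / 1e12, tolerance = 1e-12)
  ## dGv -> 0: barrier diverges and kills the rate
  expect_identical(nucleationBarrier(1, 0), Inf)
  expect_equal(nucleationRate(1e27, 1e-3, 150, 1e-12, Inf), 0)
  expect_error(nucleationBarrier(-1, 1), "positive")
})

test_that("nucleation rate has the right units and unit-cancellation value", {
  ## rho = 1 nm^-3, gamma/kBT = 1 nm^-2, D = 1 nm^2/s, dW = 0 -> 1 nm^-3 s^-1
  T <- 150
  gamma <- kBoltzmann * T * 1e18          # so gamma/(kB T) = 1 nm^-2 in SI
  N <- nucleationRate(rhoLiq = 1e27, gamma = gamma, T = T,
                      D = 1e-18, dW = 0)
  expect_equal(N, 1, tolerance = 1e-12)
  ## linearity in D
  N2 <- nucleationRate(1e27, gamma, T, 2e-18, 0)
  expect_equal(N2 / N, 2, tolerance = 1e-12)
})

test_that("growth rate limits: melting point zero, saturation, clamping", {
  expect_equal(growthRate(1e-12, 1e27, 1e27, 0, 150), 0)
  ## saturation at rhoCr = rhoLiq: U -> A_U = D * rho^(1/3)
  expect_equal(growthRate(1e-12, 1e27, 1e27, 1e-18, 150),
               1e-12 * 1e9, tolerance = 1e-6)
  ## direct arithmetic at dG/kBT = 1
  dg <- kBoltzmann * 150
  expect_equal(growthRate(1e-12, 1e27, 1e27, dg, 150),
               1e-12 * 1e9 * (1 - exp(-1)), tolerance = 1e-12)
  ## negative driving force clamps with a warning
  expect_warning(u <- growthRate(1e-12, 1e27, 1e27, -1e-21, 150), "clamped")
  expect_equal(u, 0)
  expect_error(growthRate(1e-12, 1e27, 1e27, 1e-21, 150, f = 2), "f must")
})

test_that("assembled rate curves obey the boundary and shape properties", {
  tc <- makeThermoCurves(Tm = 150, dHm = 1.5 * kBoltzmann * 150,
                         Tgrid = seq(60, 150, 1))
  vft <- VFTParams(log10invD0 = 10.68, B = 520, T0 = 35)
  res <- rateCurves(tc, 2.53, vft)
  n <- length(res@temperature)
  ## at Tm: U = 0 exactly, N suppressed to 0 by the infinite barrier
  expect_equal(res@U[n], 0)
  expect_equal(res@N[n], 0)
  expect_identical(res@dW[n], Inf)
  ## single interior maximum of N (dense-grid scan)
  iMax <- which.max(res@N)
  expect_gt(iMax, 1); expect_lt(iMax, n)
  signs <- sign(diff(res@N))
  expect_equal(sum(diff(signs[signs != 0]) != 0), 1)   # one sign change
  ## N peaks below U (slow dynamics pushes nucleation deeper)
  expect_lt(res@argmaxN, res@argmaxU)
  ## gamma enters as the Turnbull curve, equal to gammaM at Tm
  expect_equal(res@gamma[n], 2.53, tolerance = 1e-9)
})

test_that("rates are linear in D and N/D is diffusion-free", {
  tc <- makeThermoCurves(Tm = 150, dHm = 1.5 * kBoltzmann * 150,
                         Tgrid = seq(60, 150, 1))
  vft <- VFTParams(log10invD0 = 10.68, B = 520, T0 = 35)
  vftX10 <- VFTParams(log10invD0 = 10.68 - 1, B = 520, T0 = 35)
  a <- rateCurves(tc, 2.53, vft)
  b <- rateCurves(tc, 2.53, vftX10)
  ok <- a@N > 0
  expect_equal(b@N[ok] / a@N[ok], rep(10, sum(ok)), tolerance = 1e-9)
  okU <- a@U > 0
  expect_equal(b@U[okU] / a@U[okU], rep(10, sum(okU)), tolerance = 1e-9)
  ## identical N/D despite different dynamics
  expect_equal(nOverD(b)$N_over_D, nOverD(a)$N_over_D, tolerance = 1e-9)
})

test_that("constant-gamma mode and result table are available", {
  tc <- makeThermoCurves(Tm = 150, dHm = 1.5 * kBoltzmann * 150,
                         Tgrid = seq(60, 150, 2))
  vft <- VFTParams(log10invD0 = 10.68, B = 520, T0 = 35)
  rc <- rateCurves(tc, 2.53, vft, gammaMode = "constant")
  expect_true(all(rc@gamma == 2.53))
  tab <- asTable(rc)
  expect_true(all(c("T_K", "N_per_nm3_s", "U_m_per_s", "N_over_D") %in%
                  names(tab)))
  expect_equal(nrow(tab), length(rc@temperature))
})
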