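test_that("neighbor lists respect cutoffs, periodicity and FCC coordination", {
  fr <- makeFrame(rbind(c(5, 5, 5), c(5.3, 5, 5)), box = c(10, 10, 10))
  nb <- findNeighbors(fr, cutoff = 0.5)
  expect_equal(neighborIds(nb, 1), 2L)
  expect_equal(neighborIds(nb, 2), 1L)
  ## periodic pair at distance 0.2 across the boundary
  frp <- makeFrame(rbind(c(0.1, 0, 0), c(9.9, 0, 0)), box = c(10, 10, 10))
  nbp <- findNeighbors(frp, cutoff = 0.5)
  expect_equal(sqrt(sum(neighborDisplacements(nbp, 1)[1, ]^2)), 0.2,
               tolerance = 1e-12)
  ## ideal FCC: cutoff at the first-shell midpoint gives exactly 12
  a <- 0.72
  fcc <- fccFrame(4L, a)
  mid <- (a / sqrt(2) + a) / 2
  nbf <- findNeighbors(fcc, cutoff = mid)
  expect_true(all(lengths(nbf@idx) == 12L))
  ## cutoff beyond half the box is ambiguous
  expect_error(findNeighbors(fr, cutoff = 6), "half")
})

test_that("q6 of a single-neighbor molecule is exactly 1", {
  ## addition theorem collapses the contraction for one bond direction
  set.seed(5)
  for (i in 1:5) {
    dir <- rnorm(3); dir <- 0.4 * dir / sqrt(sum(dir^2))
    fr <- makeFrame(rbind(c(5, 5, 5), c(5, 5, 5) + dir), box = c(10, 10, 10))
    of <- steinhardtQ(fr, findNeighbors(fr, k = 1), averaged = FALSE)
    expect_equal(orderValues(of), c(1, 1), tolerance = 1e-12)
  }
})

test_that("ideal-FCC q6 matches the direct spherical-harmonic-sum oracle", {
  oracle <- steinhardtOracle(fccShellDirections(), 6)
  ## frozen independent reference value for the 12 ideal FCC directions
  expect_equal(oracle, 0.574524259714070, tolerance = 1e-12)
  fcc <- fccFrame(4L, 0.72)
  of <- steinhardtQ(fcc, findNeighbors(fcc, k = 12), averaged = FALSE)
  expect_equal(orderValues(of), rep(oracle, nMolecules(fcc)),
               tolerance = 1e-10)
  ## averaged variant equals plain q6 on a perfect lattice
  ofa <- steinhardtQ(fcc, findNeighbors(fcc, k = 12), averaged = TRUE)
  expect_equal(orderValues(ofa), orderValues(of), tolerance = 1e-10)
  ## q4 on the same lattice against the same oracle construction
  of4 <- steinhardtQ(fcc, findNeighbors(fcc, k = 12), l = 4,
                     averaged = FALSE)
  expect_equal(orderValues(of4)[1], steinhardtOracle(fccShellDirections(), 4),
               tolerance = 1e-10)
})

test_that("order field is invariant under global rotation and translation", {
  fr <- biphasicFixture(seed = 3, nPerPhase = 108L)
  ## compare in an enlarged cube (cloud far from the boundary) so the
  ## k-NN geometry is identical with and without the rotation; a tiny
  ## jitter breaks the exact distance ties of the ideal lattice, which
  ## would otherwise make the k-NN cut itself ambiguous
  set.seed(41)
  xyz <- positions(fr) + matrix(rnorm(3 * nMolecules(fr), sd = 0.01),
                                ncol = 3)
  ctr <- boxEdges(fr) / 2
  big <- max(boxEdges(fr)) * 3
  center <- function(m) sweep(sweep(m, 2, ctr), 2, rep(big / 2, 3), `+`)
  fr0 <- makeFrame(center(xyz), box = rep(big, 3))
  ref <- orderValues(steinhardtQ(fr0, findNeighbors(fr0, k = 12)))
  for (s in 1:3) {
    R <- randomRotation(s)
    rot <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, rep(big / 2, 3), `+`)
    frR <- makeFrame(rot, box = rep(big, 3))
    expect_lt(max(abs(positions(frR) - rot)), 1e-12)   # no wrap occurred
    vR <- orderValues(steinhardtQ(frR, findNeighbors(frR, k = 12)))
    expect_equal(vR, ref, tolerance = 1e-10)
  }
  ## translation with periodic wrap (same jittered cloud in the original
  ## periodic box, compared against its own untranslated values)
  frP <- makeFrame(xyz, box = boxEdges(fr))
  refP <- orderValues(steinhardtQ(frP, findNeighbors(frP, k = 12)))
  shift <- c(1.7, -2.3, 0.4)
  frT <- makeFrame(sweep(xyz, 2, shift, `+`), box = boxEdges(fr))
  vT <- orderValues(steinhardtQ(frT, findNeighbors(frT, k = 12)))
  expect_equal(vT, refP, tolerance = 1e-10)
})

test_that("thermal jitter strictly decreases the mean averaged q6 of FCC", {
  a <- 0.72
  means <- vapply(c(0.02, 0.05, 0.09) * a, function(amp) {
    fr <- fccFrame(3L, a, jitter = amp, seed = 8)
    mean(orderValues(steinhardtQ(fr, findNeighbors(fr, k = 12))))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("random gas has low averaged q6 and classification recovers labels", {
  ## uniform-random gas: mean averaged q6 well below the solid level
  set.seed(14)
  gas <- makeFrame(matrix(runif(3 * 400, 0, 7), ncol = 3), box = rep(7, 3))
  qg <- orderValues(steinhardtQ(gas, findNeighbors(gas, k = 12)))
  expect_lt(mean(qg), 0.25)
  ## biphasic fixture: default threshold recovers >= 95% of labels
  fr <- biphasicFixture(seed = 11)
  of <- steinhardtQ(fr, findNeighbors(fr, k = 12))
  lab <- classifyPhase(of)
  expect_gte(mean(lab == moleculeLabels(fr)), 0.95)
  ## threshold extremes
  expect_true(all(classifyPhase(of, threshold = 0) == "solid"))
  labHi <- classifyPhase(of, threshold = 1)
  expect_true(all(labHi[orderValues(of) < 1] == "liquid"))
})

test_that("isolated molecules are flagged with a warning", {
  fr <- makeFrame(rbind(c(1, 1, 1), c(1.3, 1, 1), c(8, 8, 8)),
                  box = c(16, 16, 16))
  nb <- findNeighbors(fr, cutoff = 1)
  expect_warning(of <- steinhardtQ(fr, nb), "isolated")
  expect_true(of@flagged[3])
  expect_true(is.na(orderValues(of)[3]))
  expect_equal(classifyPhase(of, threshold = 0.5)[3], "unknown")
})
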