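test_that("mixing concatenates frames in order with the right composition label", {
  spec <- familySpec(nIsoforms = 1, nResidues = 6,
                     states = c("free", "cis", "ts"), nFrames = 10,
                     baseNoise = 0.2, seed = 8)
  a <- generateModeEnsemble(spec, 1, "free")
  b <- generateModeEnsemble(spec, 1, "cis")
  ts <- generateModeEnsemble(spec, 1, "ts")
  m <- mixEnsembles(a, b)
  expect_equal(nFrames(m), 20L)
  expect_identical(coords(m)[1:10, , ], coords(a))
  expect_identical(coords(m)[11:20, , ], coords(b))
  expect_equal(stateLabel(m), "binding")
  expect_equal(stateLabel(mixEnsembles(b, ts)), "catalysis")

  other <- randomEnsemble(nRes = 7, nFrames = 10, seed = 8)
  expect_error(mixEnsembles(a, methods::initialize(other,
    isoform = isoformId(a))), "atom records")
})

test_that("mixing an ensemble with itself leaves the RMSF profile unchanged", {
  e <- randomEnsemble(nRes = 8, nFrames = 40, sigma = 0.3, seed = 21)
  r1 <- backboneRMSF(superposeEnsemble(e))
  r2 <- backboneRMSF(superposeEnsemble(mixEnsembles(e, e)))
  expect_equal(profileValues(r2), profileValues(r1), tolerance = 1e-9)
})

test_that("superposition removes rigid motion exactly", {
  base <- buildBackbone(c(NA, runif(9, -170, 170)),
                        c(runif(9, -170, 170), NA))
  arr <- array(NA_real_, c(6, nAtoms(base), 3))
  set.seed(31)
  for (f in 1:6) {
    R <- randomRotation()
    arr[f, , ] <- coords(base)[1, , ] %*% t(R) +
      matrix(rnorm(3, sd = 5), nAtoms(base), 3, byrow = TRUE)
  }
  e <- methods::initialize(base, coords = arr)
  s <- superposeEnsemble(e)
  mu <- meanStructure(s)
  for (f in 1:6)
    expect_lt(sqrt(mean(rowSums((coords(s)[f, , ] - mu)^2))), 1e-9)
})

test_that("the mean of two identical frames is the frame itself", {
  base <- buildBackbone(c(NA, -60, -60), c(-45, -45, NA))
  arr <- array(NA_real_, c(2, nAtoms(base), 3))
  arr[1, , ] <- arr[2, , ] <- coords(base)[1, , ]
  s <- superposeEnsemble(methods::initialize(base, coords = arr))
  expect_equal(meanStructure(s), coords(base)[1, , ], tolerance = 1e-12)
})

test_that("superposition RMSD matches the closed-form quaternion oracle", {
  for (seed in 1:10) {
    e <- randomEnsemble(nRes = 10, nFrames = 8, sigma = 0.4, seed = seed)
    s <- superposeEnsemble(e)
    mu <- meanStructure(s)
    for (f in c(1, 4, 8)) {
      fitted <- sqrt(mean(rowSums((coords(s)[f, , ] - mu)^2)))
      oracle <- hornFitRMSD(coords(e)[f, , ], mu)
      expect_lt(abs(fitted - oracle), 1e-9)
    }
  }
})

test_that("degenerate and unsuperposed inputs are rejected", {
  lineXYZ <- cbind(1:4, 0, 0)
  arr <- array(NA_real_, c(2, 4, 3))
  arr[1, , ] <- arr[2, , ] <- lineXYZ
  collinear <- new("BackboneEnsemble", coords = arr,
                   atoms = data.frame(resno = 1L, resname = "GLY",
                                      atom = c("N", "CA", "C", "O")),
                   isoform = "line", state = "free")
  expect_error(superposeEnsemble(collinear), "collinear")

  e <- randomEnsemble(nRes = 5, nFrames = 3)
  expect_error(backboneRMSF(e), "superposed")
  one <- methods::initialize(e, coords = coords(e)[1, , , drop = FALSE])
  expect_error(superposeEnsemble(one), "two frames")
})

test_that("RMSF is zero for identical frames and recovers isotropic noise as sigma*sqrt(3)", {
  base <- buildBackbone(c(NA, runif(19, -170, 170)),
                        c(runif(19, -170, 170), NA))
  arr <- array(NA_real_, c(3, nAtoms(base), 3))
  for (f in 1:3) arr[f, , ] <- coords(base)[1, , ]
  s <- superposeEnsemble(methods::initialize(base, coords = arr))
  expect_true(all(profileValues(backboneRMSF(s)) < 1e-9))

  spec <- familySpec(nIsoforms = 1, nResidues = 40, states = "free",
                     nFrames = 2000, baseNoise = 0.5, seed = 17)
  e <- superposeEnsemble(generateModeEnsemble(spec, 1, "free"))
  r <- backboneRMSF(e)
  expect_lt(abs(mean(profileValues(r)) - 0.5 * sqrt(3)), 0.03)
})

test_that("a hotspot with elevated noise dominates the RMSF profile", {
  noise <- matrix(0.2, 60, 1)
  noise[25:28, ] <- 0.6
  spec <- familySpec(nIsoforms = 1, nResidues = 60, states = "free",
                     nFrames = 400, noise = noise, seed = 19)
  r <- backboneRMSF(superposeEnsemble(generateModeEnsemble(spec, 1, "free")))
  expect_true(which.max(profileValues(r)) %in% 25:28)
})

test_that("maximal-gap shifting reproduces the worked examples and the brute-force oracle", {
  x1 <- c(10, 20, 30)
  expect_equal(diff(shiftAngles(x1)), diff(x1))
  expect_equal(var(shiftAngles(x1)), 100)
  expect_equal(var(shiftAngles(x1)), bruteForceShiftVar(x1))

  x2 <- c(-179, 179)
  s2 <- shiftAngles(x2)
  expect_equal(abs(diff(s2)), 2)
  expect_equal(var(s2), 2)
  expect_equal(var(s2), bruteForceShiftVar(x2))

  x3 <- c(-90, 0, 90, 180)
  expect_equal(var(shiftAngles(x3)), 13500)
  # every cut of the equally spaced set gives the same variance
  expect_equal(bruteForceShiftVar(x3), 13500)

  expect_identical(shiftAngles(c(5, 5, 5)), c(5, 5, 5))
  expect_error(shiftAngles(c(3, NA)), "at least two finite")
})

test_that("shifted variance is invariant to 360-degree wraps and common rotations", {
  set.seed(55)
  for (k in 1:50) {
    x <- runif(30, -180, 180)
    v0 <- var(shiftAngles(x))
    wrap <- x + sample(c(-360, 0, 360), 30, replace = TRUE)
    expect_equal(var(shiftAngles(wrap)), v0, tolerance = 1e-9)
    rot <- wrapDeg(x + runif(1, -180, 180))
    expect_equal(var(shiftAngles(rot)), v0, tolerance = 1e-9)
  }
})

test_that("for half-circle-confined samples shifting equals unwrapping about the circular mean", {
  set.seed(77)
  for (k in 1:20) {
    ctr <- runif(1, -180, 180)
    x <- wrapDeg(ctr + runif(15, -80, 80))
    mu <- circularMeanDeg(x)
    unwrapped <- mu + wrapDeg(x - mu)
    expect_equal(var(shiftAngles(x)), var(unwrapped), tolerance = 1e-9)
  }
})

test_that("angular variance takes the per-residue maximum over available dihedrals", {
  phi <- c(-10, 0, 10)        # variance 100
  psi <- c(-5, 0, 5)          # variance 25
  chi <- c(-7, 0, 7)          # variance 49
  d <- makeDihedralSeries(cbind(phi, psi, chi), resno = c(1, 1, 1),
                          type = c("phi", "psi", "chi1"))
  expect_equal(unname(profileValues(angularVarianceProfile(d))), 100)

  dGly <- makeDihedralSeries(cbind(c(-2, 0, 2), c(-3, 0, 3)),
                             resno = c(1, 1), type = c("phi", "psi"))
  expect_equal(unname(profileValues(angularVarianceProfile(dGly))), 9)

  dConst <- makeDihedralSeries(cbind(rep(12, 4), rep(-170, 4)),
                               resno = c(1, 1), type = c("phi", "psi"))
  expect_equal(unname(profileValues(angularVarianceProfile(dConst))), 0)

  # residue whose every series is degenerate is flagged missing
  dNA <- makeDihedralSeries(cbind(c(-2, 0, 2), rep(NA_real_, 3)),
                            resno = c(1, 2), type = c("psi", "phi"))
  av <- angularVarianceProfile(dNA)
  expect_true(is.na(profileValues(av)[2]))
  expect_false(is.na(profileValues(av)[1]))
})

test_that("state concatenation captures between-state shifts (law of total variance)", {
  a <- generateDihedralSeries(0, 6, 400, seed = 1)
  b <- generateDihedralSeries(40, 6, 400, seed = 2)
  vMix <- profileValues(angularVarianceProfile(concatDihedralSeries(a, b)))
  vA <- profileValues(angularVarianceProfile(a))
  vB <- profileValues(angularVarianceProfile(b))
  expect_gt(vMix, (vA + vB) / 2)
})

test_that("profiles restricted by an alignment map report universal columns only", {
  spec <- familySpec(nIsoforms = 1, nResidues = 5, states = "free",
                     nFrames = 50, baseNoise = 0.3, seed = 23)
  e <- generateModeEnsemble(spec, 1, "free")
  map <- buildEquivalenceMap(c(iso1 = "MKL-VQ", other = "MKLAV-"))
  r <- backboneRMSF(superposeEnsemble(e), map)
  expect_equal(profileColumns(r), c(1L, 2L, 3L, 5L))
  av <- angularVarianceProfile(extractBackboneDihedrals(e), map)
  expect_true(all(profileColumns(av) %in% c(1L, 2L, 3L, 5L)))
})
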