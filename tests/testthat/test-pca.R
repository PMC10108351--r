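# A small already-superposed ensemble displaced exactly along one
# internal mode: the cleanest probe of the eigendecomposition itself.
rankOneEnsemble <- function(nRes = 10L, amplitudes = seq(-1, 1, 0.25)) {
  spec <- familySpec(nIsoforms = 1, nResidues = nRes, states = "free",
                     nFrames = 5,
                     modes = list(list(weights = rep(1 / sqrt(nRes), nRes),
                                       sigma = 1)),
                     baseNoise = 0, seed = 3)
  ref <- generateModeEnsemble(spec, 1, "free")
  mode <- plantedModes(spec)[[1]]
  base <- as.vector(t(coords(ref)[1, , ]))
  n <- length(amplitudes)
  arr <- array(NA_real_, c(n, nAtoms(ref), 3))
  for (f in seq_len(n)) {
    flat <- base + amplitudes[f] * mode
    arr[f, , ] <- matrix(flat, ncol = 3, byrow = TRUE)
  }
  mu <- apply(arr, c(2, 3), mean)
  list(e = methods::initialize(ref, coords = arr, superposed = TRUE,
                               refMean = mu),
       mode = mode)
}

test_that("a rank-one ensemble concentrates all variance on PC1", {
  ro <- rankOneEnsemble()
  m <- cartesianPCA(ro$e)
  expect_equal(varianceFraction(m)[1], 1, tolerance = 1e-10)
  expect_true(all(eigenValues(m)[-1] < 1e-10 * eigenValues(m)[1]))
  expect_gt(abs(sum(eigenVectors(m)[, 1] * ro$mode)), 1 - 1e-10)
})

test_that("PCA recovers a planted dominant mode in the presence of noise", {
  spec <- familySpec(nIsoforms = 1, nResidues = 40, states = "free",
                     nFrames = 2000,
                     modes = list(list(weights = rep(1 / sqrt(40), 40),
                                       sigma = 1)),
                     baseNoise = 0.1, seed = 5)
  e <- superposeEnsemble(generateModeEnsemble(spec, 1, "free"))
  m <- cartesianPCA(e)
  expect_gt(abs(sum(eigenVectors(m)[, 1] * plantedModes(spec)[[1]])), 0.99)
})

test_that("eigenvalues satisfy the trace identity and match projection variances", {
  e <- superposeEnsemble(randomEnsemble(nRes = 6, nFrames = 60,
                                        sigma = 0.3, seed = 41))
  m <- cartesianPCA(e)
  X <- matrix(aperm(coords(e), c(3, 2, 1)), nrow = 60, byrow = TRUE)
  expect_equal(sum(eigenValues(m)), sum(apply(X, 2, var)),
               tolerance = 1e-6)
  for (i in 1:5)
    expect_equal(var(scores(m)[, i]), eigenValues(m)[i],
                 tolerance = 1e-9)
})

test_that("PCA is invariant to frame order", {
  e <- superposeEnsemble(randomEnsemble(nRes = 5, nFrames = 40,
                                        sigma = 0.3, seed = 47))
  set.seed(1)
  perm <- sample(40)
  ep <- methods::initialize(e, coords = coords(e)[perm, , ])
  m1 <- cartesianPCA(e)
  m2 <- cartesianPCA(ep)
  expect_equal(eigenValues(m1), eigenValues(m2), tolerance = 1e-9)
  expect_equal(eigenVectors(m1)[, 1:5], eigenVectors(m2)[, 1:5],
               tolerance = 1e-6)
})

test_that("PCA rejects ensembles that are unsuperposed or too short", {
  e <- randomEnsemble(nRes = 5, nFrames = 10)
  expect_error(cartesianPCA(e), "superposed")
  ro <- rankOneEnsemble(amplitudes = 0)
  expect_error(cartesianPCA(ro$e), "two frames")
})

test_that("dihedral PCA puts a single varying angle on PC1", {
  varying <- as.vector(dihedralValues(generateDihedralSeries(0, 10, 200,
                                                             seed = 2)))
  d <- makeDihedralSeries(cbind(varying, rep(30, 200), rep(-60, 200)),
                          resno = c(1, 1, 2),
                          type = c("phi", "psi", "phi"))
  m <- dihedralPCA(d)
  expect_equal(abs(eigenVectors(m)[1, 1]), 1, tolerance = 1e-12)
  expect_equal(eigenValues(m)[2], 0, tolerance = 1e-12)
})

test_that("circular shifting makes dihedral PCA invariant to wrap-crossing rotation", {
  set.seed(12)
  base <- matrix(rnorm(300 * 3, sd = 8), 300, 3)
  wrapped <- wrapDeg(sweep(base, 2, c(-179, 175, -178), "+"))
  centered <- wrapDeg(sweep(base, 2, c(0, 10, -20), "+"))
  dW <- makeDihedralSeries(wrapped, resno = c(1, 1, 2),
                           type = c("phi", "psi", "phi"))
  dC <- makeDihedralSeries(centered, resno = c(1, 1, 2),
                           type = c("phi", "psi", "phi"))
  expect_equal(eigenValues(dihedralPCA(dW)), eigenValues(dihedralPCA(dC)),
               tolerance = 1e-9)
  # trace identity on the shifted coordinates
  m <- dihedralPCA(dW)
  expect_equal(sum(eigenValues(m)),
               sum(apply(wrapped, 2, function(v) var(shiftAngles(v)))),
               tolerance = 1e-9)
})

test_that("dihedral PCA tolerates constant series but rejects all-constant input", {
  d <- makeDihedralSeries(cbind(rep(1, 50), rep(2, 50)),
                          resno = c(1, 1), type = c("phi", "psi"))
  expect_error(dihedralPCA(d), "constant")
  dChi <- makeDihedralSeries(matrix(rnorm(50), 50), resno = 1,
                             type = "chi1")
  expect_error(dihedralPCA(dChi), "phi/psi")
})

test_that("residue contributions are normalized and localize a block-supported mode", {
  w <- numeric(40)
  w[18:21] <- 0.5
  spec <- familySpec(nIsoforms = 1, nResidues = 40, states = "free",
                     nFrames = 2000,
                     modes = list(list(weights = w, sigma = 1)),
                     baseNoise = 0.02, seed = 6)
  e <- superposeEnsemble(generateModeEnsemble(spec, 1, "free"))
  m <- cartesianPCA(e)
  contrib <- residuePCContributions(m, 1)
  expect_equal(sum(profileValues(contrib)), 1, tolerance = 1e-12)
  expect_gt(sum(profileValues(contrib)[18:21]), 0.99)

  ro <- rankOneEnsemble(nRes = 12)
  cu <- residuePCContributions(cartesianPCA(ro$e), 1)
  # contributions must equal the planted mode's per-residue energy
  resKey <- rep(rep(1:12, each = 4), each = 3)
  expected <- vapply(1:12, function(r) sum(ro$mode[resKey == r]^2),
                     numeric(1))
  expect_equal(unname(profileValues(cu)), expected, tolerance = 1e-9)
  expect_error(residuePCContributions(m, 10^6), "outside")
})

test_that("RMSIP calibrates to 1 for identical and 0 for disjoint subspaces", {
  e <- superposeEnsemble(randomEnsemble(nRes = 6, nFrames = 40,
                                        sigma = 0.3, seed = 51))
  m <- cartesianPCA(e)
  expect_equal(rmsip(m, m), 1, tolerance = 1e-12)

  lab <- data.frame(resno = rep(1:10, each = 3),
                    atom = "CA", axis = rep(c("x", "y", "z"), 10))
  mk <- function(cols) {
    V <- diag(30)[, cols, drop = FALSE]
    new("PCAModel", center = numeric(30), values = rep(1, length(cols)),
        vectors = V, labels = lab,
        varFraction = rep(1 / length(cols), length(cols)),
        scores = matrix(0, 2, length(cols)),
        scoreGroups = c("", ""), space = "cartesian")
  }
  a <- mk(1:10); b <- mk(11:20)
  expect_equal(rmsip(a, b), 0)
  expect_equal(rmsip(a, b), rmsip(b, a))

  # sign flips do not change the subspace
  flipped <- a
  flipped@vectors[, 3] <- -flipped@vectors[, 3]
  expect_equal(rmsip(a, flipped), 1, tolerance = 1e-12)

  bad <- b
  bad@labels$atom <- "N"
  expect_error(rmsip(a, bad), "labels")
  expect_error(rmsip(a, b, n = 99), "components")
})

test_that("joint PCA of an ensemble with itself reproduces its own PCs", {
  spec <- familySpec(nIsoforms = 1, nResidues = 8, states = "free",
                     nFrames = 50, baseNoise = 0.3, seed = 61)
  e <- generateModeEnsemble(spec, 1, "free")
  joint <- jointPCA(list(e, e))
  single <- cartesianPCA(superposeEnsemble(e))
  # identical coordinate sets up to labeling; compare eigenvectors
  expect_equal(joint@vectors[, 1:10], single@vectors[, 1:10],
               tolerance = 1e-6)
  expect_equal(sqrt(sum(crossprod(joint@vectors[, 1:10],
                                  single@vectors[, 1:10])^2) / 10),
               1, tolerance = 1e-9)
  expect_equal(as.integer(table(scoreGroups(joint))), 100L)
})

test_that("joint PCA separates ensembles displaced along a known vector", {
  spec <- familySpec(nIsoforms = 1, nResidues = 10,
                     states = c("free", "cis"), nFrames = 300,
                     modes = list(list(weights = rep(sqrt(0.1), 10),
                                       sigma = 0.15)),
                     baseNoise = 0.1, seed = 71)
  a <- generateModeEnsemble(spec, 1, "free")
  b <- generateModeEnsemble(spec, 1, "cis")
  mode <- plantedModes(spec)[[1]]
  shift <- 2 * mode
  arr <- coords(b)
  for (f in seq_len(nFrames(b)))
    arr[f, , ] <- arr[f, , ] + matrix(shift, ncol = 3, byrow = TRUE)
  b <- methods::initialize(b, coords = arr)
  joint <- jointPCA(list(a, b))
  expect_gt(abs(sum(eigenVectors(joint)[, 1] * mode)), 0.95)
  g <- scoreGroups(joint)
  mA <- mean(scores(joint)[g == paste0(isoformId(a), ":free"), 1])
  mB <- mean(scores(joint)[g == paste0(isoformId(b), ":cis"), 1])
  expect_lt(mA * mB, 0)
  expect_equal(sum(g == paste0(isoformId(a), ":free")), nFrames(a))
})

test_that("a rigidified state samples a smaller projected area", {
  mkPair <- function(freeNoise, seed) {
    noise <- matrix(c(freeNoise, 0.3), 12, 2, byrow = TRUE)
    spec <- familySpec(nIsoforms = 1, nResidues = 12,
                       states = c("free", "cis"), nFrames = 250,
                       noise = noise, seed = seed)
    list(free = generateModeEnsemble(spec, 1, "free"),
         cis = generateModeEnsemble(spec, 1, "cis"))
  }
  wt <- mkPair(0.45, 81)
  mut <- mkPair(0.15, 81)
  jWT <- jointPCA(list(wt$free, wt$cis))
  jMut <- jointPCA(list(mut$free, mut$cis))
  g <- paste0("iso1", ":free")
  ratio <- projectionHullArea(jMut, g) / projectionHullArea(jWT, g)
  expect_lt(ratio, 1)
})

test_that("PCA models survive TSV/JSON serialization", {
  e <- superposeEnsemble(randomEnsemble(nRes = 5, nFrames = 30,
                                        sigma = 0.3, seed = 91))
  m <- cartesianPCA(e)
  prefix <- file.path(withr::local_tempdir(), "model")
  writePCAModel(m, prefix)
  m2 <- readPCAModel(prefix)
  expect_equal(eigenValues(m2), eigenValues(m))
  expect_equal(eigenVectors(m2), eigenVectors(m)[, 1:10],
               tolerance = 1e-9)
  expect_equal(rmsip(m2, m2), 1, tolerance = 1e-12)
  expect_equal(scores(m2), scores(m), tolerance = 1e-9)
})
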