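## Independent oracles used across the suite.  These deliberately share
## no code with the package: the rigid fit uses Horn's closed-form
## quaternion solution instead of SVD, the circular mean works on the
## raw samples, and the shift oracle enumerates every candidate cut.

# Optimal superposition RMSD via the largest eigenvalue of Horn's 4x4
# quaternion matrix.
hornFitRMSD <- function(mobile, target) {
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(target, 2, colMeans(target))
  S <- crossprod(X, Y)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max((sum(X^2) + sum(Y^2) - 2 * lmax) / nrow(X), 0))
}

circularMeanDeg <- function(x) {
  r <- x * pi / 180
  m <- atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
  if (m <= -180) m + 360 else m
}

wrapDeg <- function(x) {
  w <- x - 360 * round(x / 360)
  w[w <= -180] <- w[w <= -180] + 360
  w
}

# Minimum achievable sample variance over every candidate circular cut
# (each gap midpoint), by exhaustive enumeration.
bruteForceShiftVar <- function(x) {
  s <- sort(unique(wrapDeg(x)))
  if (length(s) <= 1L) return(0)
  k <- length(s)
  mids <- c((s[-k] + s[-1]) / 2, wrapDeg((s[k] + s[1] + 360) / 2))
  vars <- vapply(mids, function(cut) {
    var(cut + (wrapDeg(x) - cut) %% 360)
  }, numeric(1))
  min(vars)
}

# Forward-kinematics oracle for the CA(i) -> C -> N -> CA(i+1) virtual
# bond under planar trans (omega = 180) geometry: a 2D zigzag with the
# published bond lengths and angles.
fkVirtualCACADistance <- function(bCAC = 1.525, bCN = 1.329,
                                  bNCA = 1.458, aCACN = 116.2,
                                  aCNCA = 121.7) {
  turn1 <- (180 - aCACN) * pi / 180
  turn2 <- (180 - aCNCA) * pi / 180
  p1 <- c(bCAC, 0)
  d1 <- c(cos(turn1), sin(turn1))
  p2 <- p1 + bCN * d1
  d2 <- c(cos(turn1 - turn2), sin(turn1 - turn2))
  p3 <- p2 + bNCA * d2
  sqrt(sum(p3^2))
}

# Small random internal-motion ensemble around the package's reference
# chain, used by superposition and PCA tests.
randomEnsemble <- function(nRes = 12L, nFrames = 20L, sigma = 0.3,
                           seed = 1L) {
  spec <- familySpec(nIsoforms = 1L, nResidues = nRes, states = "free",
                     nFrames = nFrames, baseNoise = sigma, seed = seed)
  generateModeEnsemble(spec, 1L, "free")
}

randomRotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

applyRigid <- function(e, R, t) {
  arr <- coords(e)
  for (f in seq_len(dim(arr)[1]))
    arr[f, , ] <- arr[f, , ] %*% t(R) + matrix(t, dim(arr)[2], 3,
                                               byrow = TRUE)
  methods::initialize(e, coords = arr)
}

makeDihedralSeries <- function(columns, resno, type, isoform = "iso1",
                               state = "free") {
  new("DihedralSeries", values = columns,
      info = data.frame(resno = as.integer(resno), type = type),
      isoform = isoform, state = state)
}

makeProfile <- function(values, columns = seq_along(values),
                        metric = "rmsf", isoform = "iso1",
                        composition = "binding") {
  new("FlexibilityProfile", metric = metric, values = values,
      columns = as.integer(columns), isoform = isoform,
      composition = composition)
}

makeEnergySeries <- function(x, state, label = "synthetic") {
  new("EnergySeries", state = state, dG = x,
      index = seq_along(x), label = label)
}
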