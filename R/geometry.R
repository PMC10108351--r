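## Low-level vector geometry shared by the builder, the dihedral
## extractor and the superposition engine.  Angles are degrees
## everywhere at the interface; radians never leak out.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

## Map angles onto the package-wide convention (-180, 180].
.wrapAngle <- function(x) {
  w <- x - 360 * round(x / 360)
  w[w <= -180] <- w[w <= -180] + 360
  w
}

.rowCross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

## Torsion about p2-p3 for row-parallel point matrices (n x 3), IUPAC
## sign convention, degrees in (-180, 180].  Collinear defining atoms
## give NA.
.dihedral <- function(p1, p2, p3, p4, tol = 1e-10) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .rowCross(b1, b2)
  n2 <- .rowCross(b2, b3)
  b2n <- sqrt(rowSums(b2^2))
  m1 <- .rowCross(n1, b2 / b2n)
  x <- rowSums(n1 * n2)
  y <- -rowSums(m1 * n2)
  ang <- .rad2deg(atan2(y, x))
  bad <- sqrt(rowSums(n1^2)) < tol | sqrt(rowSums(n2^2)) < tol | b2n < tol
  ang[bad] <- NA_real_
  .wrapAngle(ang)
}

## Natural-extension (internal-coordinate) placement: position atom D
## given the three preceding atoms, the C-D bond length, the B-C-D bond
## angle and the A-B-C-D torsion (degrees).
.placeAtom <- function(A, B, C, d, theta, tau) {
  th <- .deg2rad(theta)
  ta <- .deg2rad(tau)
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10)
    stop("degenerate internal-coordinate frame: collinear reference atoms")
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + d * (-bc * cos(th) + m * cos(ta) * sin(th) + n * sin(ta) * sin(th))
}

## Least-squares rigid fit (Kabsch, SVD): rotation + translation taking
## mobile onto target; returns the transformed coordinates.
.rigidFit <- function(mobile, target) {
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  Xc <- sweep(mobile, 2, cm)
  Yc <- sweep(target, 2, ct)
  H <- crossprod(Xc, Yc)
  s <- svd(H)
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(Xc %*% R, 2, ct, "+")
}
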