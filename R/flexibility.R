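.compositionLabel <- function(a, b) {
  if (a == "free" && b == "cis") return("binding")
  if (a == "cis" && b == "ts") return("catalysis")
  paste(a, b, sep = "+")
}

#' Concatenate two ensembles of the same isoform into a mixed ensemble
#'
#' Frames of \code{a} are followed by frames of \code{b}, with no
#' reweighting; the composition label records the mixture
#' (free+cis = \code{"binding"}, cis+ts = \code{"catalysis"}).  Mixing
#' before computing flexibility metrics lets cross-state mean shifts
#' contribute to the measured variance.
#'
#' @param a,b [BackboneEnsemble-class] objects with identical atom
#'   records and isoform.
#' @param equalize subsample the longer member (deterministic, evenly
#'   spaced) to the shorter's length before concatenating.
#' @return an unsuperposed mixed [BackboneEnsemble-class].
#' @export
mixEnsembles <- function(a, b, equalize = FALSE) {
  stopifnot(is(a, "BackboneEnsemble"), is(b, "BackboneEnsemble"))
  if (a@isoform != b@isoform)
    stop("cannot mix ensembles from different isoforms")
  if (!identical(a@atoms, b@atoms))
    stop("atom records of the two ensembles do not match")
  ca <- a@coords; cb <- b@coords
  if (equalize) {
    n <- min(dim(ca)[1], dim(cb)[1])
    pick <- function(x) {
      idx <- round(seq(1, dim(x)[1], length.out = n))
      x[idx, , , drop = FALSE]
    }
    ca <- pick(ca); cb <- pick(cb)
  }
  arr <- array(NA_real_, c(dim(ca)[1] + dim(cb)[1], dim(ca)[2], 3L))
  arr[seq_len(dim(ca)[1]), , ] <- ca
  arr[dim(ca)[1] + seq_len(dim(cb)[1]), , ] <- cb
  new("BackboneEnsemble", coords = arr, atoms = a@atoms,
      isoform = a@isoform, state = .compositionLabel(a@state, b@state))
}

#' Concatenate two dihedral series over states
#'
#' @param a,b [DihedralSeries-class] objects with identical
#'   (residue, angle-type) keys.
#' @export
concatDihedralSeries <- function(a, b) {
  stopifnot(is(a, "DihedralSeries"), is(b, "DihedralSeries"))
  if (!identical(a@info, b@info))
    stop("dihedral keys of the two series do not match")
  new("DihedralSeries", values = rbind(a@values, b@values), info = a@info,
      isoform = a@isoform, state = .compositionLabel(a@state, b@state))
}

#' Iteratively superpose an ensemble onto its mean structure
#'
#' All frames are least-squares rigid-fit (over all backbone atoms) onto
#' the current mean, the mean is recomputed, and the cycle repeats until
#' the mean moves less than \code{tol} (RMS displacement, angstrom) or
#' \code{maxIter} iterations.  The converged mean is stored on the
#' result and available via [meanStructure()].
#'
#' @param e a [BackboneEnsemble-class] with at least two frames.
#' @param tol convergence tolerance on the mean, angstrom.
#' @param maxIter iteration cap.
#' @return the superposed ensemble.
#' @export
superposeEnsemble <- function(e, tol = 1e-6, maxIter = 10L) {
  stopifnot(is(e, "BackboneEnsemble"))
  nf <- nFrames(e)
  if (nf < 2L) stop("at least two frames are required for superposition")
  f1 <- e@coords[1, , ]
  sv <- svd(sweep(f1, 2, colMeans(f1)))$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate ensemble: atoms are collinear")
  frames <- lapply(seq_len(nf), function(f) e@coords[f, , ])
  ref <- frames[[1]]
  for (it in seq_len(maxIter)) {
    frames <- lapply(frames, .rigidFit, target = ref)
    newRef <- Reduce(`+`, frames) / nf
    shift <- sqrt(mean(rowSums((newRef - ref)^2)))
    ref <- newRef
    if (shift < tol) break
  }
  arr <- array(NA_real_, dim(e@coords))
  for (f in seq_len(nf)) arr[f, , ] <- frames[[f]]
  methods::initialize(e, coords = arr, superposed = TRUE, refMean = ref)
}

#' Per-residue backbone RMSF profile
#'
#' Root-mean-square fluctuation of each atom about its mean position
#' over the superposed frames, averaged arithmetically over the four
#' backbone heavy atoms (N, CA, C, O) of each residue; side-chain atoms
#' are excluded.  With an alignment map the profile is reported on
#' universal alignment columns only.
#'
#' @param e a superposed [BackboneEnsemble-class] (see
#'   [superposeEnsemble()]); unsuperposed input is rejected.
#' @param map optional [AlignmentMap-class]; requires the ensemble's
#'   isoform to be present.
#' @return a [FlexibilityProfile-class] with metric \code{"rmsf"}.
#' @export
backboneRMSF <- function(e, map = NULL) {
  stopifnot(is(e, "BackboneEnsemble"))
  if (!e@superposed)
    stop("RMSF requires a superposed ensemble; call superposeEnsemble() first")
  at <- e@atoms
  mu <- e@refMean
  dev2 <- matrix(0, nFrames(e), nAtoms(e))
  for (f in seq_len(nFrames(e)))
    dev2[f, ] <- rowSums((e@coords[f, , ] - mu)^2)
  rmsfAtom <- sqrt(colMeans(dev2))
  bb <- at$atom %in% c("N", "CA", "C", "O")
  resno <- sort(unique(at$resno))
  rmsfRes <- vapply(resno, function(r)
    mean(rmsfAtom[bb & at$resno == r]), numeric(1))
  if (is.null(map)) {
    cols <- as.integer(resno)
  } else {
    rc <- residueColumn(map, e@isoform)
    if (length(rc) != length(resno))
      stop(sprintf("alignment map has %d residues for isoform %s but the ensemble has %d",
                   length(rc), e@isoform, length(resno)))
    cols <- rc[match(resno, seq_along(rc))]
    keep <- cols %in% universalColumns(map)
    cols <- cols[keep]; rmsfRes <- rmsfRes[keep]
  }
  new("FlexibilityProfile", metric = "rmsf", values = rmsfRes,
      columns = as.integer(cols), isoform = e@isoform,
      composition = e@state)
}

#' Maximal-gap circular shifting of angle series
#'
#' Accounts for the circular nature of dihedral data before linear
#' statistics (as in dPCA+): values are sorted on the circle, the
#' largest gap between circularly consecutive values is found (ties
#' resolved by the gap whose midpoint lies closest to +180 degrees, then
#' by the smallest midpoint), the circle is cut at that gap's midpoint,
#' and all values are unwrapped into one contiguous interval of width at
#' most 360 degrees.  Input order is preserved; NA values pass through.
#'
#' @param x numeric angles, degrees; at least two finite values unless
#'   all are identical.
#' @return shifted angles, same length and order.
#' @export
shiftAngles <- function(x) {
  fin <- is.finite(x)
  v <- x[fin]
  if (length(v) < 2L)
    stop("at least two finite values are required")
  if (length(unique(v)) == 1L) return(x)
  s <- sort(unique(.wrapAngle(v)))
  k <- length(s)
  gaps <- c(diff(s), s[1] + 360 - s[k])
  mids <- .wrapAngle(c((s[-k] + s[-1]) / 2, (s[k] + s[1] + 360) / 2))
  best <- which(gaps == max(gaps))
  if (length(best) > 1L) {
    d180 <- abs(180 - mids[best])
    d180 <- pmin(d180, 360 - d180)
    best <- best[d180 == min(d180)]
    if (length(best) > 1L) best <- best[which.min(mids[best])]
  }
  cut <- mids[best]
  out <- x
  w <- .wrapAngle(v)
  out[fin] <- cut + (w - cut) %% 360
  out
}

#' Per-residue angular-variance profile
#'
#' For each (residue, angle-type) series -- already concatenated over
#' the composition's states -- the sample variance (n-1 denominator) of
#' the maximal-gap-shifted angles is computed; per residue, the maximum
#' over its available dihedrals (phi, psi, chi1) is taken as the
#' residue's angular variance (deg^2).  Residues with no usable dihedral
#' are reported NA.
#'
#' @param d a [DihedralSeries-class].
#' @param map optional [AlignmentMap-class] restricting the report to
#'   universal columns.
#' @return a [FlexibilityProfile-class] with metric \code{"angvar"}.
#' @export
angularVarianceProfile <- function(d, map = NULL) {
  stopifnot(is(d, "DihedralSeries"))
  perDih <- vapply(seq_len(ncol(d@values)), function(j) {
    v <- d@values[, j]
    v <- v[is.finite(v)]
    if (length(v) < 2L) return(NA_real_)
    stats::var(shiftAngles(v))
  }, numeric(1))
  res <- sort(unique(d@info$resno))
  perRes <- vapply(res, function(r) {
    vv <- perDih[d@info$resno == r]
    vv <- vv[is.finite(vv)]
    if (!length(vv)) NA_real_ else max(vv)
  }, numeric(1))
  if (is.null(map)) {
    cols <- as.integer(res)
  } else {
    rc <- residueColumn(map, d@isoform)
    cols <- rc[res]
    keep <- cols %in% universalColumns(map)
    cols <- cols[keep]; perRes <- perRes[keep]
  }
  new("FlexibilityProfile", metric = "angvar", values = perRes,
      columns = as.integer(cols), isoform = d@isoform,
      composition = d@state)
}
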