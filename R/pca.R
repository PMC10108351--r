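## Shared eigendecomposition core.  Covariance uses the sample (n-1)
## denominator; rank deficiency (frames < coordinates) is handled by the
## symmetric eigendecomposition with eigenvalues clamped at >= 0; the
## eigenvector sign is fixed by making the largest-magnitude loading
## positive so reports are reproducible.
.pcaFromMatrix <- function(X, labels, space, nScores = 10L,
                           groups = NULL) {
  if (nrow(X) < 2L) stop("PCA requires at least two frames")
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  C <- crossprod(Xc) / (nrow(X) - 1L)
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  V <- eg$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  k <- min(nScores, ncol(V))
  scores <- Xc %*% V[, seq_len(k), drop = FALSE]
  if (is.null(groups)) groups <- rep("", nrow(X))
  new("PCAModel", center = center, values = ev, vectors = V,
      labels = labels, varFraction = if (sum(ev) > 0) ev / sum(ev) else ev,
      scores = scores, scoreGroups = as.character(groups), space = space)
}

#' Cartesian PCA of a superposed backbone ensemble
#'
#' Principal components of the covariance of flattened backbone
#' coordinates (N, CA, C, O; side-chain atoms excluded), eigenvalues
#' descending.  Per-frame projections onto the leading components are
#' centered and stored on the model.
#'
#' @param e a superposed [BackboneEnsemble-class] with >= 2 frames.
#' @param nScores number of leading components to project onto.
#' @return a [PCAModel-class].
#' @export
cartesianPCA <- function(e, nScores = 10L) {
  stopifnot(is(e, "BackboneEnsemble"))
  if (!e@superposed)
    stop("Cartesian PCA requires a superposed ensemble")
  bb <- which(e@atoms$atom %in% c("N", "CA", "C", "O"))
  X <- .flattenFrames(e@coords[, bb, , drop = FALSE])
  at <- e@atoms[bb, ]
  labels <- data.frame(resno = rep(at$resno, each = 3L),
                       atom = rep(at$atom, each = 3L),
                       axis = rep(c("x", "y", "z"), length(bb)))
  .pcaFromMatrix(X, labels, "cartesian", nScores = nScores)
}

#' Dihedral PCA of phi/psi angle series
#'
#' Each phi/psi series is circularly shifted (maximal-gap cut, see
#' [shiftAngles()]) before the variance-covariance matrix of the angles
#' is built and diagonalized, so wrap-crossing series contribute their
#' true variance.  chi1 angles are not part of the dihedral PCA
#' coordinate set.  Constant series are allowed (zero row/column); an
#' all-constant input is rejected.
#'
#' @param d a [DihedralSeries-class].
#' @param nScores number of leading components to project onto.
#' @return a [PCAModel-class] with (residue, angle-type) coordinate
#'   labels.
#' @export
dihedralPCA <- function(d, nScores = 10L) {
  stopifnot(is(d, "DihedralSeries"))
  keep <- d@info$type %in% c("phi", "psi")
  if (!any(keep)) stop("no phi/psi series available")
  V <- d@values[, keep, drop = FALSE]
  if (anyNA(V)) {
    ok <- stats::complete.cases(V)
    V <- V[ok, , drop = FALSE]
  }
  if (nrow(V) < 2L) stop("PCA requires at least two complete frames")
  shifted <- apply(V, 2, shiftAngles)
  if (all(apply(shifted, 2, function(v) diff(range(v)) == 0)))
    stop("all dihedral series are constant")
  .pcaFromMatrix(shifted, d@info[keep, , drop = FALSE], "dihedral",
                 nScores = nScores)
}

#' Per-residue contributions to a principal component
#'
#' The contribution of a residue is the sum of squared loadings of its
#' coordinates on the chosen PC, normalized to sum to one over
#' positions -- the quantity used to locate the residues driving the
#' dominant collective motion.
#'
#' @param model a [PCAModel-class].
#' @param component PC index.
#' @param map optional [AlignmentMap-class]; contributions are then
#'   reported on universal alignment columns of \code{isoform}.
#' @param isoform isoform id used with \code{map} and stored on the
#'   profile.
#' @return a [FlexibilityProfile-class] with metric
#'   \code{"contribution"}.
#' @export
residuePCContributions <- function(model, component = 1L, map = NULL,
                                   isoform = "model") {
  stopifnot(is(model, "PCAModel"))
  if (component < 1L || component > ncol(model@vectors))
    stop("component index outside the model")
  v2 <- model@vectors[, component]^2
  key <- if ("column" %in% names(model@labels)) "column" else "resno"
  res <- sort(unique(model@labels[[key]]))
  contrib <- vapply(res, function(r)
    sum(v2[model@labels[[key]] == r]), numeric(1))
  contrib <- contrib / sum(contrib)
  cols <- as.integer(res)
  if (!is.null(map) && key == "resno") {
    rc <- residueColumn(map, isoform)
    cols <- rc[res]
    keep <- cols %in% universalColumns(map)
    cols <- cols[keep]
    contrib <- contrib[keep] / sum(contrib[keep])
  }
  new("FlexibilityProfile", metric = "contribution", values = contrib,
      columns = cols, isoform = isoform,
      composition = paste0("PC", component))
}

#' Root mean square inner product of two PC subspaces
#'
#' \code{sqrt((1/n) sum_{i<=n} sum_{j<=n} (a_i . b_j)^2)} over the top
#' \code{n} components: 1 for identical subspaces, 0 for orthogonal
#' ones.
#'
#' @param a,b [PCAModel-class] objects over identical coordinate labels.
#' @param n subspace dimension (default 10).
#' @return scalar in [0, 1].
#' @export
rmsip <- function(a, b, n = 10L) {
  stopifnot(is(a, "PCAModel"), is(b, "PCAModel"))
  if (!identical(a@labels, b@labels))
    stop("coordinate labels of the two models do not match")
  if (ncol(a@vectors) < n || ncol(b@vectors) < n)
    stop(sprintf("both models need at least %d components", n))
  A <- a@vectors[, seq_len(n), drop = FALSE]
  B <- b@vectors[, seq_len(n), drop = FALSE]
  sqrt(sum(crossprod(A, B)^2) / n)
}

## Restrict an ensemble to the N/CA/C/O atoms of residues mapping to
## universal alignment columns, reordered by column.
.restrictToUniversal <- function(e, map) {
  rc <- residueColumn(map, e@isoform)
  uni <- universalColumns(map)
  resKeep <- which(rc %in% uni)
  ord <- resKeep[order(match(rc[resKeep], uni))]
  idx <- integer(0); cols <- integer(0); atomNm <- character(0)
  for (r in ord) {
    for (nm in c("N", "CA", "C", "O")) {
      idx <- c(idx, which(e@atoms$resno == r & e@atoms$atom == nm)[1])
      cols <- c(cols, rc[r]); atomNm <- c(atomNm, nm)
    }
  }
  list(coords = e@coords[, idx, , drop = FALSE],
       labels = data.frame(column = rep(cols[seq(1, length(cols), by = 4)],
                                        each = 12L),
                           atom = rep(rep(c("N", "CA", "C", "O"),
                                          each = 3L), length(ord)),
                           axis = rep(c("x", "y", "z"), length(idx))))
}

#' Joint PCA over multiple ensembles
#'
#' Each ensemble is restricted to the backbone atoms of universal
#' alignment columns, all frames are concatenated and iteratively
#' superposed onto the joint mean, and a single PCA is computed over the
#' concatenation.  Per-frame projections are labeled by source ensemble
#' (isoform:state), supporting state-overlap comparisons in the PC1/PC2
#' plane.
#'
#' @param ensembles list of >= 2 [BackboneEnsemble-class] objects.
#' @param map an [AlignmentMap-class] covering every ensemble's isoform;
#'   may be \code{NULL} when all ensembles share identical atom records.
#' @param nScores number of leading components to project onto.
#' @return a [PCAModel-class] whose \code{scoreGroups} name the source
#'   ensembles.
#' @export
jointPCA <- function(ensembles, map = NULL, nScores = 10L) {
  if (length(ensembles) < 2L)
    stop("joint PCA requires at least two ensembles")
  if (!is.null(map) && !length(universalColumns(map)))
    stop("the universal column set is empty")
  parts <- lapply(ensembles, function(e) {
    stopifnot(is(e, "BackboneEnsemble"))
    if (is.null(map)) {
      bb <- which(e@atoms$atom %in% c("N", "CA", "C", "O"))
      at <- e@atoms[bb, ]
      list(coords = e@coords[, bb, , drop = FALSE],
           labels = data.frame(column = rep(at$resno, each = 3L),
                               atom = rep(at$atom, each = 3L),
                               axis = rep(c("x", "y", "z"), length(bb))))
    } else .restrictToUniversal(e, map)
  })
  lab <- parts[[1]]$labels
  for (p in parts[-1])
    if (!identical(dim(p$coords)[2], dim(parts[[1]]$coords)[2]))
      stop("ensembles do not restrict to a common coordinate set")
  nf <- vapply(parts, function(p) dim(p$coords)[1], integer(1))
  natoms <- dim(parts[[1]]$coords)[2]
  arr <- array(NA_real_, c(sum(nf), natoms, 3L))
  off <- 0L
  for (p in parts) {
    arr[off + seq_len(dim(p$coords)[1]), , ] <- p$coords
    off <- off + dim(p$coords)[1]
  }
  groups <- rep(vapply(ensembles, function(e)
    paste(e@isoform, e@state, sep = ":"), character(1)), nf)
  joint <- new("BackboneEnsemble", coords = arr,
               atoms = data.frame(resno = rep(seq_len(natoms %/% 4L),
                                              each = 4L),
                                  resname = "GLY",
                                  atom = rep(c("N", "CA", "C", "O"),
                                             natoms %/% 4L)),
               isoform = "joint", state = "joint")
  joint <- superposeEnsemble(joint)
  X <- .flattenFrames(joint@coords)
  .pcaFromMatrix(X, lab, "cartesian", nScores = nScores, groups = groups)
}

#' Convex-hull area of a group's projection cloud
#'
#' Area of the convex hull of one source ensemble's projections in a
#' two-PC plane; hull-area ratios quantify how much conformational
#' space a state samples relative to another.
#'
#' @param model a [PCAModel-class] with grouped scores (see
#'   [jointPCA()]).
#' @param group a scoreGroups label.
#' @param comps the two components spanning the plane.
#' @return hull area (score units squared).
#' @export
projectionHullArea <- function(model, group, comps = c(1L, 2L)) {
  stopifnot(is(model, "PCAModel"))
  sel <- model@scoreGroups == group
  if (!any(sel)) stop(sprintf("no projections for group %s", group))
  P <- model@scores[sel, comps, drop = FALSE]
  h <- grDevices::chull(P)
  xs <- P[h, 1]; ys <- P[h, 2]
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}

#' Serialize and restore PCA models as TSV + JSON
#'
#' Writes \code{<prefix>_model.json} (metadata), and TSV matrices
#' \code{<prefix>_eigenvalues.tsv}, \code{<prefix>_center.tsv},
#' \code{<prefix>_labels.tsv}, \code{<prefix>_vectors.tsv} (leading
#' \code{nVectors} components) and \code{<prefix>_scores.tsv}.
#'
#' @param model a [PCAModel-class].
#' @param prefix output path prefix.
#' @param nVectors number of eigenvectors to store (default 10, enough
#'   for the usual RMSIP comparisons).
#' @export
writePCAModel <- function(model, prefix, nVectors = 10L) {
  stopifnot(is(model, "PCAModel"))
  k <- min(nVectors, ncol(model@vectors))
  jsonlite::write_json(
    list(space = model@space, nCoordinates = nrow(model@vectors),
         nComponentsStored = k, nFrames = nrow(model@scores)),
    paste0(prefix, "_model.json"), auto_unbox = TRUE, digits = NA)
  wt <- function(x, name)
    utils::write.table(x, paste0(prefix, "_", name, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(data.frame(eigenvalue = model@values), "eigenvalues")
  wt(data.frame(center = model@center), "center")
  wt(model@labels, "labels")
  V <- model@vectors[, seq_len(k), drop = FALSE]
  colnames(V) <- paste0("PC", seq_len(k))
  wt(as.data.frame(V), "vectors")
  S <- model@scores
  colnames(S) <- paste0("PC", seq_len(ncol(S)))
  wt(cbind(data.frame(group = model@scoreGroups), as.data.frame(S)),
     "scores")
  invisible(prefix)
}

#' @rdname writePCAModel
#' @export
readPCAModel <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_model.json"),
                              simplifyVector = TRUE)
  rd <- function(name) utils::read.delim(paste0(prefix, "_", name, ".tsv"))
  ev <- rd("eigenvalues")$eigenvalue
  V <- as.matrix(rd("vectors"))
  sc <- rd("scores")
  new("PCAModel", center = rd("center")$center, values = ev,
      vectors = unname(V), labels = rd("labels"),
      varFraction = if (sum(ev) > 0) ev / sum(ev) else ev,
      scores = unname(as.matrix(sc[, -1, drop = FALSE])),
      scoreGroups = as.character(sc$group), space = meta$space)
}
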