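#' Pairwise profile correlation across isoforms
#'
#' Pearson correlation between the flexibility profiles of every isoform
#' pair over shared positions (pairwise-complete when a profile has
#' missing positions), plus the mean off-diagonal correlation used as
#' the single-number conservation summary.  A zero-variance profile
#' yields undefined (NA) entries, which are excluded from the mean with
#' a message.
#'
#' @param profiles list of >= 2 [FlexibilityProfile-class] objects with
#'   a common metric and composition.
#' @return a [ConservationMatrix-class].
#' @export
profileCorrelationMatrix <- function(profiles) {
  if (length(profiles) < 2L)
    stop("at least two profiles are required")
  metrics <- vapply(profiles, metricLabel, character(1))
  comps <- vapply(profiles, stateLabel, character(1))
  if (length(unique(metrics)) != 1L || length(unique(comps)) != 1L)
    stop("profiles must share one metric and one composition")
  ids <- vapply(profiles, isoformId, character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  n <- length(profiles)
  r <- diag(1, n)
  dimnames(r) <- list(ids, ids)
  nUndef <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pi <- profiles[[i]]; pj <- profiles[[j]]
    shared <- intersect(pi@columns, pj@columns)
    vi <- pi@values[match(shared, pi@columns)]
    vj <- pj@values[match(shared, pj@columns)]
    ok <- is.finite(vi) & is.finite(vj)
    if (sum(ok) < 3L)
      stop(sprintf("profiles %s and %s share fewer than 3 positions",
                   ids[i], ids[j]))
    if (stats::sd(vi[ok]) == 0 || stats::sd(vj[ok]) == 0) {
      r[i, j] <- r[j, i] <- NA_real_
      nUndef <- nUndef + 1L
    } else {
      r[i, j] <- r[j, i] <- stats::cor(vi[ok], vj[ok])
    }
  }
  if (nUndef > 0L)
    message(sprintf("%d undefined correlation pair(s) excluded from the mean",
                    nUndef))
  off <- r[upper.tri(r)]
  new("ConservationMatrix", r = r, metric = metrics[1],
      composition = comps[1], meanR = mean(off, na.rm = TRUE),
      nUndefined = nUndef)
}

#' Identify consensus key dynamic residues across isoforms
#'
#' Within each isoform's profile, positions exceeding
#' mean + zThreshold * SD are flagged (an isoform with a constant
#' profile contributes no flags).  The consensus score of a position is
#' the fraction of isoforms flagging it; positions with score >=
#' consensusMin are selected and merged into maximal contiguous
#' intervals, operationalizing the by-inspection identification of
#' high-flexibility regions such as the gatekeeper loops.
#'
#' @param profiles list of [FlexibilityProfile-class] objects (one per
#'   isoform) on a common position set.
#' @param zThreshold z-score cutoff within each isoform (default 2).
#' @param consensusMin minimum consensus score; default is a strict
#'   majority of the isoforms.
#' @return a [KeyRegionReport-class].
#' @export
identifyKeyRegions <- function(profiles, zThreshold = 2,
                               consensusMin = NULL) {
  if (!length(profiles)) stop("no profiles supplied")
  if (zThreshold <= 0) stop("zThreshold must be positive")
  n <- length(profiles)
  if (is.null(consensusMin)) consensusMin <- (floor(n / 2) + 1) / n
  cols <- sort(Reduce(union, lapply(profiles, profileColumns)))
  flags <- matrix(FALSE, n, length(cols))
  ids <- vapply(profiles, isoformId, character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  rownames(flags) <- ids
  colnames(flags) <- cols
  for (i in seq_len(n)) {
    p <- profiles[[i]]
    v <- p@values[is.finite(p@values)]
    if (length(v) < 2L || stats::sd(v) == 0) next
    thr <- mean(v) + zThreshold * stats::sd(v)
    hit <- p@columns[which(p@values > thr)]
    flags[i, match(hit, cols)] <- TRUE
  }
  score <- colMeans(flags)
  selected <- cols[score >= consensusMin]
  regions <- data.frame(start = integer(0), end = integer(0))
  if (length(selected)) {
    breaks <- c(0L, which(diff(selected) > 1L), length(selected))
    regions <- do.call(rbind, lapply(seq_len(length(breaks) - 1L),
      function(k) data.frame(start = selected[breaks[k] + 1L],
                             end = selected[breaks[k + 1L]])))
  }
  new("KeyRegionReport", score = unname(score), columns = as.integer(cols),
      selected = as.integer(selected), regions = regions, flags = flags,
      zThreshold = as.numeric(zThreshold),
      consensusMin = as.numeric(consensusMin))
}
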