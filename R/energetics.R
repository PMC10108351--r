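#' Read a per-frame binding-energy table
#'
#' Two-column TSV (\code{sample_index}, \code{dG} in kcal/mol), e.g.
#' per-frame MM-PBSA output.  Non-numeric or non-finite values are
#' rejected with the offending line named.
#'
#' @param path TSV file.
#' @param state isomer state of the series (\code{cis}, \code{ts},
#'   \code{trans}); taken from a \code{# state:} header line when
#'   present.
#' @param label enzyme variant label; taken from a \code{# label:}
#'   header line when present.
#' @return an [EnergySeries-class].
#' @export
readEnergyTable <- function(path, state = NULL, label = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ln <- readLines(path)
  hdr <- grep("^#", ln, value = TRUE)
  getMeta <- function(key) {
    m <- grep(sprintf("^#\\s*%s:", key), hdr, value = TRUE)
    if (length(m)) trimws(sub(sprintf("^#\\s*%s:", key), "", m[1])) else NULL
  }
  if (is.null(state)) state <- getMeta("state")
  if (is.null(label)) label <- getMeta("label")
  if (is.null(label)) label <- basename(path)
  if (is.null(state))
    stop("state must be given as an argument or a '# state:' header")
  body <- ln[!grepl("^#", ln)]
  body <- body[nzchar(trimws(body))]
  if (grepl("^\\s*sample_index", body[1])) body <- body[-1]
  parts <- strsplit(body, "\t|\\s+")
  for (i in seq_along(parts)) {
    p <- parts[[i]][nzchar(parts[[i]])]
    if (length(p) != 2L)
      stop(sprintf("line %d: expected two columns", i))
    v <- suppressWarnings(as.numeric(p))
    if (anyNA(v) || !all(is.finite(v)))
      stop(sprintf("line %d: non-numeric or non-finite value '%s'",
                   i, p[which(!is.finite(suppressWarnings(as.numeric(p))))[1]]))
    parts[[i]] <- v
  }
  m <- do.call(rbind, parts)
  new("EnergySeries", state = state, dG = m[, 2],
      index = as.integer(m[, 1]), label = label)
}

#' @rdname readEnergyTable
#' @param s an [EnergySeries-class] to write.
#' @export
writeEnergyTable <- function(s, path) {
  stopifnot(is(s, "EnergySeries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# state: %s", s@state),
               sprintf("# label: %s", s@label),
               "sample_index\tdG"), con)
  writeLines(sprintf("%d\t%.10g", s@index, s@dG), con)
  invisible(path)
}

#' Summarize a binding-energy series
#'
#' Mean over all samples and a blocked standard error of the mean:
#' the series is split into non-overlapping blocks (the last partial
#' block dropped) and the SEM is the SD of block means over
#' sqrt(number of blocks), which remains honest when successive frames
#' are autocorrelated.
#'
#' @param s an [EnergySeries-class].
#' @param blockSize samples per block (default 10); \code{n >=
#'   2 * blockSize} is required.
#' @return list with \code{mean}, \code{sem}, \code{blockSize},
#'   \code{nBlocks} and histogram \code{breaks} for plotting parity.
#' @export
summarizeBinding <- function(s, blockSize = 10L) {
  stopifnot(is(s, "EnergySeries"))
  if (blockSize < 1L) stop("blockSize must be at least 1")
  x <- s@dG[is.finite(s@dG)]
  n <- length(x)
  if (n < 2L * blockSize)
    stop("series too short for the requested block size")
  nb <- n %/% blockSize
  bm <- colMeans(matrix(x[seq_len(nb * blockSize)], blockSize, nb))
  list(mean = mean(x),
       sem = stats::sd(bm) / sqrt(nb),
       blockSize = as.integer(blockSize), nBlocks = nb,
       breaks = graphics::hist(x, plot = FALSE)$breaks)
}

#' Assess catalysis by transition-state stabilization
#'
#' An enzyme lowers the isomerization barrier iff it binds the
#' omega = 90 degree transition state more strongly (lower binding free
#' energy) than both ground states.  With per-state means and blocked
#' SEMs, the decision margin against ground state g is
#' \code{delta_g = max(z * sqrt(SEM_ts^2 + SEM_g^2), deltaMin)}; the
#' floor \code{deltaMin} (default 0.6 kcal/mol, about RT at 300 K)
#' keeps sub-thermal mean differences from driving verdicts at large
#' sample sizes.  The verdict is \code{catalytic} when mean(ts)
#' undercuts both ground-state means by more than the margin,
#' \code{non-catalytic} when it undercuts neither by more than the
#' margin (transition-state binding no stronger than ground-state
#' binding means an unaltered -- or raised -- barrier), and
#' \code{indeterminate} when it undercuts exactly one.  Only energy
#' differences enter, so the verdict is invariant under a common
#' offset.
#'
#' @param cis,ts,trans [EnergySeries-class] objects of one variant.
#' @param z margin multiplier (default 2).
#' @param blockSize block length for the blocked SEM.
#' @param deltaMin absolute margin floor, kcal/mol.
#' @return a [CatalysisReport-class].
#' @export
assessCatalysis <- function(cis, ts, trans, z = 2, blockSize = 10L,
                            deltaMin = 0.6) {
  for (s in list(cis, ts, trans)) stopifnot(is(s, "EnergySeries"))
  if (cis@state != "cis" || ts@state != "ts" || trans@state != "trans")
    stop("series must be supplied in cis, ts, trans order with matching states")
  labs <- unique(c(cis@label, ts@label, trans@label))
  if (length(labs) != 1L)
    stop(sprintf("mixed variant labels: %s", paste(labs, collapse = ", ")))
  sc <- summarizeBinding(cis, blockSize)
  st <- summarizeBinding(ts, blockSize)
  sr <- summarizeBinding(trans, blockSize)
  means <- c(cis = sc$mean, ts = st$mean, trans = sr$mean)
  sems <- c(cis = sc$sem, ts = st$sem, trans = sr$sem)
  dCis <- unname(means["cis"] - means["ts"])
  dTrans <- unname(means["trans"] - means["ts"])
  dCisSE <- unname(sqrt(sems["ts"]^2 + sems["cis"]^2))
  dTransSE <- unname(sqrt(sems["ts"]^2 + sems["trans"]^2))
  margins <- c(cis = max(z * dCisSE, deltaMin),
               trans = max(z * dTransSE, deltaMin))
  belowCis <- means[["ts"]] < means[["cis"]] - margins[["cis"]]
  belowTrans <- means[["ts"]] < means[["trans"]] - margins[["trans"]]
  v <- if (belowCis && belowTrans) "catalytic"
       else if (!belowCis && !belowTrans) "non-catalytic"
       else "indeterminate"
  new("CatalysisReport", label = labs, means = means, sems = sems,
      blockSize = as.integer(blockSize),
      deltaCis = dCis, deltaTrans = dTrans,
      deltaCisSE = dCisSE, deltaTransSE = dTransSE,
      margins = margins, z = as.numeric(z), verdict = v)
}

#' Export a catalysis report as JSON
#'
#' Includes the schematic free-energy-diagram data: relative E+S
#' (unbound) and E/S (bound) levels per isomer state, taking the
#' unbound level as zero for every state so the bound level equals the
#' state's mean binding free energy.
#'
#' @param report a [CatalysisReport-class].
#' @param path output JSON file.
#' @export
writeCatalysisJSON <- function(report, path) {
  stopifnot(is(report, "CatalysisReport"))
  obj <- list(
    label = report@label,
    means = as.list(report@means),
    sems = as.list(report@sems),
    block_size = report@blockSize,
    delta_cis = report@deltaCis, delta_cis_se = report@deltaCisSE,
    delta_trans = report@deltaTrans, delta_trans_se = report@deltaTransSE,
    margins = list(cis = report@margins[1], trans = report@margins[2]),
    z = report@z,
    verdict = report@verdict,
    diagram = lapply(names(report@means), function(s)
      list(state = s, unbound = 0, bound = unname(report@means[[s]])))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
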