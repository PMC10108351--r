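#' Write an ensemble as a multi-model PDB file
#'
#' Strict fixed-column PDB with one MODEL/ENDMDL block per frame;
#' occupancy and B-factor columns are written as zeros.
#'
#' @param e a [BackboneEnsemble-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMultiModelPDB <- function(e, path) {
  stopifnot(is(e, "BackboneEnsemble"))
  at <- e@atoms
  elem <- substr(at$atom, 1, 1)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(e))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- e@coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    lines <- sprintf(
      "ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)), at$atom, at$resname, at$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], 0, 0, elem)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file into a BackboneEnsemble
#'
#' Parses strict fixed-column ATOM records, one frame per MODEL block
#' (a file without MODEL records is read as a single frame).  Models
#' must contain identical atom records; every residue must carry the
#' four backbone atoms N, CA, C, O.  Alternate locations and insertion
#' codes are rejected.
#'
#' @param path PDB file.
#' @param isoform,state labels stored on the ensemble (state defaults to
#'   \code{"free"}).
#' @return a [BackboneEnsemble-class].
#' @export
readMultiModelPDB <- function(path, isoform = basename(path),
                              state = "free") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ln <- readLines(path)
  rec <- substr(ln, 1, 6)
  isAtom <- rec == "ATOM  "
  if (!any(isAtom)) stop(sprintf("no ATOM records in %s", path))
  modelStarts <- which(rec == "MODEL ")
  model <- integer(length(ln))
  if (length(modelStarts)) {
    model <- findInterval(seq_along(ln), modelStarts)
    endsPassed <- findInterval(seq_along(ln), which(rec == "ENDMDL"))
    if (any(isAtom & (model - endsPassed) != 1L))
      stop("ATOM records outside MODEL/ENDMDL blocks")
  } else {
    model[isAtom] <- 1L
  }
  am <- model[isAtom]
  counts <- table(am)
  if (length(unique(counts)) != 1L) {
    ref <- as.integer(counts[1])
    bad <- as.integer(names(counts)[counts != ref][1])
    stop(sprintf("inconsistent atom count across models: model %d has %d atoms, expected %d",
                 bad, as.integer(counts[as.character(bad)]), ref))
  }
  atomLines <- ln[isAtom]
  altloc <- substr(atomLines, 17, 17)
  if (any(altloc != " "))
    stop("alternate location indicators are not supported")
  icode <- substr(atomLines, 27, 27)
  if (any(icode != " "))
    stop("insertion codes are not supported")
  name <- trimws(substr(atomLines, 13, 16))
  resname <- trimws(substr(atomLines, 18, 20))
  resno <- as.integer(substr(atomLines, 23, 26))
  x <- as.numeric(substr(atomLines, 31, 38))
  y <- as.numeric(substr(atomLines, 39, 46))
  z <- as.numeric(substr(atomLines, 47, 54))
  if (anyNA(c(x, y, z)) || anyNA(resno))
    stop("malformed ATOM record: non-numeric fixed-column field")
  nmodel <- length(counts)
  nat <- as.integer(counts[1])
  first <- am == am[1]
  at <- data.frame(resno = resno[first], resname = resname[first],
                   atom = name[first])
  if (nmodel > 1L) {
    nmMat <- matrix(name, nat, nmodel)
    rnMat <- matrix(resno, nat, nmodel)
    bad <- which(colSums(nmMat != nmMat[, 1] | rnMat != rnMat[, 1]) > 0)
    if (length(bad))
      stop(sprintf("atom records of model %d do not match model 1", bad[1]))
  }
  for (r in unique(at$resno)) {
    miss <- setdiff(c("N", "CA", "C", "O"), at$atom[at$resno == r])
    if (length(miss))
      stop(sprintf("residue %d is missing backbone atom %s", r, miss[1]))
  }
  ord <- order(am)
  arr <- array(NA_real_, c(nmodel, nat, 3L))
  arr[, , 1] <- matrix(x[ord], nmodel, nat, byrow = TRUE)
  arr[, , 2] <- matrix(y[ord], nmodel, nat, byrow = TRUE)
  arr[, , 3] <- matrix(z[ord], nmodel, nat, byrow = TRUE)
  new("BackboneEnsemble", coords = arr, atoms = at,
      isoform = isoform, state = state)
}

.gapChars <- c("-", ".")

#' Build residue equivalences from a multiple sequence alignment
#'
#' Reads a FASTA multiple alignment and maps each isoform's 1-based
#' residue numbering to 1-based alignment columns.  The universal column
#' set -- columns occupied in every isoform -- defines the positions on
#' which cross-isoform flexibility profiles are compared; positions not
#' aligned across all isoforms are thereby excluded.
#'
#' @param alignment path to an aligned FASTA file, a named character
#'   vector of equal-length aligned sequences, or a
#'   `Biostrings::AAStringSet`.
#' @param ids isoforms to include (default: all sequences).
#' @param residueCounts optional named integer vector of ensemble
#'   residue counts; a mismatch with the ungapped sequence lengths is an
#'   error.
#' @param reference optional isoform whose residue numbering labels
#'   reports.
#' @return an [AlignmentMap-class].  A warning is raised when no column
#'   is universal.
#' @export
buildEquivalenceMap <- function(alignment, ids = NULL,
                                residueCounts = NULL, reference = "") {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment)) {
    aln <- Biostrings::readAAStringSet(alignment)
    seqs <- setNames(as.character(aln), names(aln))
  } else if (methods::is(alignment, "XStringSet")) {
    seqs <- setNames(as.character(alignment), names(alignment))
  } else if (is.character(alignment)) {
    seqs <- alignment
  } else stop("unsupported alignment input")
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.null(ids)) ids <- names(seqs)
  missing <- setdiff(ids, names(seqs))
  if (length(missing))
    stop(sprintf("isoform(s) missing from the alignment: %s",
                 paste(missing, collapse = ", ")))
  seqs <- seqs[ids]
  w <- unique(nchar(seqs))
  if (length(w) != 1L)
    stop("aligned sequences differ in length")
  mats <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  maps <- lapply(mats, function(ch) which(!ch %in% .gapChars))
  if (!is.null(residueCounts)) {
    for (id in intersect(names(residueCounts), ids)) {
      if (length(maps[[id]]) != residueCounts[[id]])
        stop(sprintf(
          "isoform %s: alignment has %d residues but the ensemble has %d",
          id, length(maps[[id]]), residueCounts[[id]]))
    }
  }
  occupied <- vapply(mats, function(ch) !ch %in% .gapChars,
                     logical(w))
  universal <- which(rowSums(occupied) == length(ids))
  if (!length(universal))
    warning("no alignment column is occupied in every isoform")
  new("AlignmentMap", maps = lapply(maps, as.integer),
      universal = as.integer(universal), width = as.integer(w),
      reference = reference)
}

#' Identity alignment map for a set of equal-length isoforms
#'
#' Convenience constructor for synthetic families, where all isoforms
#' share the same residue numbering: every residue maps to its own
#' column and all columns are universal.
#'
#' @param nResidues chain length.
#' @param ids isoform identifiers.
#' @export
identityAlignmentMap <- function(nResidues, ids) {
  maps <- setNames(rep(list(seq_len(nResidues)), length(ids)), ids)
  new("AlignmentMap", maps = lapply(maps, as.integer),
      universal = seq_len(as.integer(nResidues)),
      width = as.integer(nResidues), reference = "")
}

#' Extract backbone (and chi1) dihedral time series from an ensemble
#'
#' Standard four-atom torsions under the IUPAC sign convention, degrees
#' in (-180, 180]: phi = C(i-1)-N-CA-C, psi = N-CA-C-N(i+1),
#' chi1 = N-CA-CB-G where G is the gamma atom (IUPAC priority when
#' branched).  phi is undefined for the first residue, psi for the last,
#' chi1 wherever side-chain atoms are absent.  Frames with collinear
#' defining atoms yield NA.
#'
#' @param e a [BackboneEnsemble-class].
#' @return a [DihedralSeries-class].
#' @export
extractBackboneDihedrals <- function(e) {
  stopifnot(is(e, "BackboneEnsemble"))
  at <- e@atoms
  res <- sort(unique(at$resno))
  n <- length(res)
  lookup <- function(r, nm) {
    i <- which(at$resno == r & at$atom == nm)
    if (length(i)) i[1] else NA_integer_
  }
  quads <- list(); info <- list()
  for (k in seq_len(n)) {
    r <- res[k]
    if (k > 1L) {
      quads[[length(quads) + 1L]] <-
        c(lookup(res[k - 1L], "C"), lookup(r, "N"), lookup(r, "CA"),
          lookup(r, "C"))
      info[[length(info) + 1L]] <- data.frame(resno = r, type = "phi")
    }
    if (k < n) {
      quads[[length(quads) + 1L]] <-
        c(lookup(r, "N"), lookup(r, "CA"), lookup(r, "C"),
          lookup(res[k + 1L], "N"))
      info[[length(info) + 1L]] <- data.frame(resno = r, type = "psi")
    }
    cb <- lookup(r, "CB")
    if (!is.na(cb)) {
      gnames <- intersect(.gammaAtoms, at$atom[at$resno == r])
      if (length(gnames)) {
        quads[[length(quads) + 1L]] <-
          c(lookup(r, "N"), lookup(r, "CA"), cb, lookup(r, gnames[1]))
        info[[length(info) + 1L]] <- data.frame(resno = r, type = "chi1")
      }
    }
  }
  nf <- nFrames(e)
  pt <- function(a) matrix(e@coords[, a, , drop = FALSE], nf, 3L)
  vals <- matrix(NA_real_, nf, length(quads))
  for (j in seq_along(quads)) {
    q <- quads[[j]]
    vals[, j] <- .dihedral(pt(q[1]), pt(q[2]), pt(q[3]), pt(q[4]))
  }
  new("DihedralSeries", values = vals, info = do.call(rbind, info),
      isoform = e@isoform, state = e@state)
}

#' Read and write flexibility-profile TSV files
#'
#' Profiles travel as three-column TSV: \code{alignment_column},
#' \code{residue_label}, \code{value}.
#'
#' @param x a [FlexibilityProfile-class].
#' @param path file path.
#' @param labels optional residue labels (default: the columns).
#' @export
writeProfileTSV <- function(x, path, labels = NULL) {
  stopifnot(is(x, "FlexibilityProfile"))
  if (is.null(labels)) labels <- x@columns
  utils::write.table(
    data.frame(alignment_column = x@columns, residue_label = labels,
               value = x@values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfileTSV
#' @param metric,isoform,composition metadata to attach on read.
#' @export
readProfileTSV <- function(path, metric = "rmsf", isoform = basename(path),
                           composition = "unknown") {
  d <- utils::read.delim(path)
  if (!all(c("alignment_column", "value") %in% names(d)))
    stop("profile TSV must have columns alignment_column and value")
  new("FlexibilityProfile", metric = metric,
      values = as.numeric(d$value),
      columns = as.integer(d$alignment_column),
      isoform = isoform, composition = composition)
}

#' Serialize a family specification as a JSON config
#'
#' @param spec a [FamilySpec-class].
#' @param path file path.
#' @export
writeFamilySpec <- function(spec, path) {
  stopifnot(is(spec, "FamilySpec"))
  obj <- list(nIsoforms = spec@nIsoforms, nResidues = spec@nResidues,
              nFrames = spec@nFrames, states = spec@states,
              modes = lapply(spec@modes, function(m)
                list(weights = m$weights, sigma = m$sigma)),
              noise = as.vector(spec@noise), hotspot = spec@hotspot,
              hotspotFactor = spec@hotspotFactor, rho = spec@rho,
              profileSd = spec@profileSd, baseNoise = spec@baseNoise,
              seed = spec@seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFamilySpec
#' @export
readFamilySpec <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  modes <- list()
  if (length(o$modes))
    modes <- lapply(seq_len(nrow(as.data.frame(o$modes))), function(i)
      list(weights = unlist(o$modes$weights[i]), sigma = o$modes$sigma[i]))
  familySpec(nIsoforms = o$nIsoforms, nResidues = o$nResidues,
             states = o$states, nFrames = o$nFrames, modes = modes,
             noise = matrix(o$noise, o$nResidues, length(o$states)),
             hotspot = if (length(o$hotspot)) o$hotspot else NULL,
             hotspotFactor = o$hotspotFactor, rho = o$rho,
             profileSd = o$profileSd, baseNoise = o$baseNoise,
             seed = o$seed)
}

#' Write a generated family to disk
#'
#' One multi-model PDB per isoform and state, one ground-truth profile
#' TSV per isoform, and the generating spec as JSON.
#'
#' @param family output of [generateIsoformFamily()].
#' @param spec the generating [FamilySpec-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
exportFamily <- function(family, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(family$ensembles)) {
    for (s in names(family$ensembles[[id]]))
      writeMultiModelPDB(family$ensembles[[id]][[s]],
                         file.path(dir, sprintf("%s_%s.pdb", id, s)))
    writeProfileTSV(family$profiles[[id]],
                    file.path(dir, sprintf("%s_truth.tsv", id)))
  }
  writeFamilySpec(spec, file.path(dir, "family_spec.json"))
  invisible(dir)
}
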