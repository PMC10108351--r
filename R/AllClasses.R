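#' @import methods
#' @importFrom stats cor var sd rnorm runif setNames
NULL

.validStates <- c("free", "cis", "ts", "trans")

## Gamma atoms accepted as the chi1 terminus, in IUPAC priority order.
.gammaAtoms <- c("OG", "OG1", "SG", "CG", "CG1", "CG2")

#' BackboneEnsemble: a multi-frame protein backbone coordinate set
#'
#' Holds frames x atoms x 3 Cartesian coordinates (angstrom) for the
#' backbone heavy atoms (N, CA, C, O, plus an optional CB and one gamma
#' atom per residue) of one isoform in one functional state of the
#' catalytic cycle: substrate-free (\code{free}), \code{cis}-bound,
#' transition-state-bound (\code{ts}, omega = 90 degrees) or
#' \code{trans}-bound.  Mixed ensembles built by [mixEnsembles()] carry a
#' composition label such as \code{"binding"} (free+cis) or
#' \code{"catalysis"} (cis+ts).
#'
#' @slot coords numeric array \code{[frames, atoms, 3]}, angstrom.
#' @slot atoms data.frame with columns \code{resno}, \code{resname},
#'   \code{atom}; one row per atom, residue numbering 1-based.
#' @slot isoform single character isoform identifier.
#' @slot state functional-state or composition label.
#' @slot superposed has the ensemble been least-squares superposed?
#' @slot refMean converged mean structure (atoms x 3) when superposed,
#'   otherwise a 0-row matrix.
#' @exportClass BackboneEnsemble
setClass("BackboneEnsemble",
  representation(
    coords = "array",
    atoms = "data.frame",
    isoform = "character",
    state = "character",
    superposed = "logical",
    refMean = "matrix"
  ),
  prototype(
    superposed = FALSE,
    refMean = matrix(numeric(0), 0L, 3L)
  )
)

setValidity("BackboneEnsemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    return("coords must be a frames x atoms x 3 array")
  if (d[1] < 1L)
    return("ensemble must contain at least one frame")
  if (!all(is.finite(object@coords)))
    return("coordinates must all be finite")
  at <- object@atoms
  if (!all(c("resno", "resname", "atom") %in% names(at)))
    return("atoms must have columns resno, resname, atom")
  if (nrow(at) != d[2])
    return("atom table length disagrees with coordinate array")
  for (r in unique(at$resno)) {
    nm <- at$atom[at$resno == r]
    if (!all(c("N", "CA", "C", "O") %in% nm))
      return(sprintf("residue %d lacks one of the backbone atoms N, CA, C, O", r))
    extra <- setdiff(nm, c("N", "CA", "C", "O"))
    if (length(extra) && !all(extra %in% c("CB", .gammaAtoms)))
      return(sprintf("residue %d carries unsupported atoms: %s",
                     r, paste(setdiff(extra, c("CB", .gammaAtoms)), collapse = ", ")))
    if (sum(extra %in% .gammaAtoms) > 1L)
      return(sprintf("residue %d carries more than one gamma atom", r))
  }
  if (length(object@isoform) != 1L || length(object@state) != 1L ||
      !nzchar(object@state))
    return("isoform and state must be single non-empty strings")
  if (isTRUE(object@superposed) && nrow(object@refMean) != d[2])
    return("superposed ensembles must carry a mean structure of matching size")
  TRUE
})

#' DihedralSeries: per-frame backbone/side-chain torsion angles
#'
#' Angles are stored in degrees in the interval (-180, 180], one column
#' per (residue, angle-type) pair with type one of \code{phi}, \code{psi},
#' \code{chi1}.  \code{phi} is absent for the first residue, \code{psi}
#' for the last, and \code{chi1} whenever the side-chain atoms are absent
#' (e.g. glycine).  Degenerate (collinear) frames are stored as \code{NA}.
#'
#' @slot values numeric matrix frames x dihedrals (degrees).
#' @slot info data.frame with columns \code{resno}, \code{type}.
#' @slot isoform,state provenance labels copied from the source ensemble.
#' @exportClass DihedralSeries
setClass("DihedralSeries",
  representation(
    values = "matrix",
    info = "data.frame",
    isoform = "character",
    state = "character"
  )
)

setValidity("DihedralSeries", function(object) {
  if (!all(c("resno", "type") %in% names(object@info)))
    return("info must have columns resno and type")
  if (ncol(object@values) != nrow(object@info))
    return("values and info disagree on the number of dihedrals")
  if (!all(object@info$type %in% c("phi", "psi", "chi1")))
    return("angle types must be phi, psi or chi1")
  v <- object@values[is.finite(object@values)]
  if (length(v) && (any(v <= -180 - 1e-9) || any(v > 180 + 1e-9)))
    return("angles must lie in (-180, 180] degrees")
  TRUE
})

#' AlignmentMap: residue equivalences across isoforms
#'
#' Maps each isoform's 1-based residue numbering onto 1-based columns of
#' a multiple sequence alignment.  \code{universal} holds the ordered set
#' of columns occupied (non-gap) in every isoform; cross-isoform profile
#' comparison is restricted to these columns.
#'
#' @slot maps named list; per isoform an integer vector giving the
#'   alignment column of each residue.
#' @slot universal ordered integer vector of gap-free columns.
#' @slot width alignment width (number of columns).
#' @slot reference optional isoform whose numbering labels reports
#'   ("" when unset).
#' @exportClass AlignmentMap
setClass("AlignmentMap",
  representation(
    maps = "list",
    universal = "integer",
    width = "integer",
    reference = "character"
  ),
  prototype(reference = "")
)

setValidity("AlignmentMap", function(object) {
  if (is.null(names(object@maps)) || any(!nzchar(names(object@maps))))
    return("maps must be a named list keyed by isoform id")
  for (id in names(object@maps)) {
    m <- object@maps[[id]]
    if (anyDuplicated(m))
      return(sprintf("map for isoform %s is not injective", id))
    if (length(m) && (min(m) < 1L || max(m) > object@width))
      return(sprintf("map for isoform %s exceeds the alignment width", id))
    if (!all(object@universal %in% m))
      return(sprintf("universal columns missing from isoform %s", id))
  }
  if (is.unsorted(object@universal))
    return("universal columns must be ordered")
  TRUE
})

#' FlexibilityProfile: a per-position flexibility metric
#'
#' One scalar per universal alignment column for a stated ensemble
#' composition.  Metrics: \code{rmsf} (angstrom, backbone-heavy-atom
#' average), \code{angvar} (deg^2, maximal per-residue dihedral variance
#' after circular shifting) or \code{contribution} (normalized squared PC
#' loadings).  Positions without a defined value (e.g. a residue with no
#' dihedrals) are \code{NA}.
#'
#' @slot metric one of \code{"rmsf"}, \code{"angvar"}, \code{"contribution"}.
#' @slot values numeric vector, non-negative or NA.
#' @slot columns integer alignment columns (or residue numbers when no
#'   alignment is involved), parallel to \code{values}.
#' @slot isoform isoform id.
#' @slot composition ensemble composition label (\code{"binding"},
#'   \code{"catalysis"} or a single state).
#' @exportClass FlexibilityProfile
setClass("FlexibilityProfile",
  representation(
    metric = "character",
    values = "numeric",
    columns = "integer",
    isoform = "character",
    composition = "character"
  )
)

setValidity("FlexibilityProfile", function(object) {
  if (!object@metric %in% c("rmsf", "angvar", "contribution"))
    return("metric must be rmsf, angvar or contribution")
  if (length(object@values) != length(object@columns))
    return("values and columns differ in length")
  if (any(object@values < 0, na.rm = TRUE))
    return("flexibility values must be non-negative")
  if (anyDuplicated(object@columns))
    return("duplicate positions in profile")
  TRUE
})

#' PCAModel: principal components of an ensemble
#'
#' Eigen-decomposition of the covariance of either flattened Cartesian
#' backbone coordinates or circularly shifted phi/psi dihedrals.
#' Eigenvalues are descending and clamped at zero; eigenvectors are
#' orthonormal with the sign convention that the largest-magnitude
#' loading of each PC is positive.
#'
#' @slot center coordinate mean vector.
#' @slot values eigenvalues, descending, >= 0.
#' @slot vectors coordinates x components orthonormal matrix.
#' @slot labels data.frame describing each coordinate (atom x axis for
#'   Cartesian, residue x angle-type for dihedral PCA).
#' @slot varFraction fraction of total variance per PC.
#' @slot scores centered per-frame projections (frames x components).
#' @slot scoreGroups source-ensemble label per projected frame (used by
#'   [jointPCA()]); "" for single-ensemble models.
#' @slot space \code{"cartesian"} or \code{"dihedral"}.
#' @exportClass PCAModel
setClass("PCAModel",
  representation(
    center = "numeric",
    values = "numeric",
    vectors = "matrix",
    labels = "data.frame",
    varFraction = "numeric",
    scores = "matrix",
    scoreGroups = "character",
    space = "character"
  )
)

setValidity("PCAModel", function(object) {
  if (is.unsorted(rev(object@values)))
    return("eigenvalues must be in descending order")
  if (any(object@values < 0))
    return("eigenvalues must be non-negative")
  if (nrow(object@vectors) != length(object@center))
    return("eigenvector dimension disagrees with the center vector")
  if (nrow(object@labels) != nrow(object@vectors))
    return("coordinate labels disagree with eigenvector dimension")
  k <- min(ncol(object@vectors), 25L)   # spot-check; full Gram is O(p^3)
  g <- crossprod(object@vectors[, seq_len(k), drop = FALSE])
  if (k && max(abs(g - diag(k))) > 1e-8)
    return("eigenvectors are not orthonormal within 1e-8")
  TRUE
})

#' ConservationMatrix: pairwise dynamical similarity of isoforms
#'
#' Pearson correlations between per-position flexibility profiles of
#' isoform pairs, over shared universal alignment columns, plus the mean
#' off-diagonal correlation used as the single-number conservation
#' summary.
#'
#' @slot r symmetric correlation matrix with unit diagonal; undefined
#'   entries (a zero-variance profile) are NA.
#' @slot metric,composition labels of the compared profiles.
#' @slot meanR mean off-diagonal correlation (NA entries excluded).
#' @slot nUndefined number of undefined off-diagonal pairs excluded.
#' @exportClass ConservationMatrix
setClass("ConservationMatrix",
  representation(
    r = "matrix",
    metric = "character",
    composition = "character",
    meanR = "numeric",
    nUndefined = "integer"
  )
)

setValidity("ConservationMatrix", function(object) {
  r <- object@r
  if (nrow(r) != ncol(r)) return("correlation matrix must be square")
  if (max(abs(r - t(r)), na.rm = TRUE) > 1e-12)
    return("correlation matrix must be symmetric")
  if (any(abs(diag(r) - 1) > 1e-12, na.rm = TRUE))
    return("diagonal must be 1")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    return("correlations must lie in [-1, 1]")
  TRUE
})

#' KeyRegionReport: consensus key dynamic residues
#'
#' Positions whose flexibility (or PC contribution) exceeds
#' mean + z * SD within each isoform, scored by the fraction of isoforms
#' flagging them, thresholded by a consensus rule and merged into maximal
#' contiguous intervals.
#'
#' @slot score per-position consensus score in [0, 1].
#' @slot columns positions scored (universal alignment columns).
#' @slot selected positions passing the consensus threshold.
#' @slot regions data.frame(start, end): maximal disjoint intervals of
#'   selected positions.
#' @slot flags isoform x position logical flag matrix.
#' @slot zThreshold,consensusMin thresholds used.
#' @exportClass KeyRegionReport
setClass("KeyRegionReport",
  representation(
    score = "numeric",
    columns = "integer",
    selected = "integer",
    regions = "data.frame",
    flags = "matrix",
    zThreshold = "numeric",
    consensusMin = "numeric"
  )
)

setValidity("KeyRegionReport", function(object) {
  if (!all(object@selected %in% object@columns))
    return("selected positions must be scored positions")
  if (nrow(object@regions)) {
    if (any(object@regions$start > object@regions$end))
      return("malformed region interval")
    o <- order(object@regions$start)
    s <- object@regions$start[o]; e <- object@regions$end[o]
    if (nrow(object@regions) > 1L && any(s[-1] <= e[-length(e)] + 1L))
      return("regions must be maximal and disjoint")
  }
  TRUE
})

#' EnergySeries: per-frame binding free energies for one isomer state
#'
#' Ordered per-sample binding free energies (kcal/mol) between an enzyme
#' variant and its substrate in one omega-isomer state of the catalytic
#' cycle (cis, transition state, or trans), e.g. MM-PBSA per-frame
#' output.
#'
#' @slot state one of \code{"cis"}, \code{"ts"}, \code{"trans"}.
#' @slot dG binding free energies, kcal/mol.
#' @slot index sample indices (frame numbers).
#' @slot label enzyme variant label (e.g. \code{"CypE_WT"}).
#' @exportClass EnergySeries
setClass("EnergySeries",
  representation(
    state = "character",
    dG = "numeric",
    index = "integer",
    label = "character"
  )
)

setValidity("EnergySeries", function(object) {
  if (!object@state %in% c("cis", "ts", "trans"))
    return("state must be cis, ts or trans")
  if (sum(is.finite(object@dG)) < 2L)
    return("at least two finite energy samples are required")
  if (length(object@index) != length(object@dG))
    return("index and dG differ in length")
  TRUE
})

#' CatalysisReport: transition-state-stabilization verdict
#'
#' Summarizes per-state mean binding free energies with blocked standard
#' errors and renders a catalysis verdict: the enzyme lowers the
#' isomerization barrier iff it binds the omega = 90 degree transition
#' state more strongly than both ground states by more than the noise
#' margin delta = z * sqrt(SEM_ts^2 + SEM_ground^2).
#'
#' @slot label enzyme variant.
#' @slot means,sems named per-state (cis, ts, trans) means and blocked
#'   standard errors, kcal/mol.
#' @slot blockSize block length used for the blocked SEM.
#' @slot deltaCis,deltaTrans barrier-change estimates mean(ground) -
#'   mean(ts), kcal/mol, with propagated standard errors.
#' @slot deltaCisSE,deltaTransSE propagated uncertainties.
#' @slot margins named decision margins (cis, trans).
#' @slot z margin multiplier.
#' @slot verdict \code{"catalytic"}, \code{"non-catalytic"} or
#'   \code{"indeterminate"}.
#' @exportClass CatalysisReport
setClass("CatalysisReport",
  representation(
    label = "character",
    means = "numeric",
    sems = "numeric",
    blockSize = "integer",
    deltaCis = "numeric",
    deltaTrans = "numeric",
    deltaCisSE = "numeric",
    deltaTransSE = "numeric",
    margins = "numeric",
    z = "numeric",
    verdict = "character"
  )
)

setValidity("CatalysisReport", function(object) {
  if (!object@verdict %in% c("catalytic", "non-catalytic", "indeterminate"))
    return("invalid verdict")
  if (any(object@sems < 0)) return("SEMs must be non-negative")
  TRUE
})

#' FamilySpec: parameters of a synthetic isoform family
#'
#' Declares the synthetic study conditions: family size, chain length,
#' functional states, planted collective modes, per-residue noise,
#' an optional flexibility hotspot shared by all isoforms, and the
#' conservation level rho (the fraction of per-residue amplitude
#' variance shared across isoforms).
#'
#' @slot nIsoforms,nResidues,nFrames counts.
#' @slot states subset of free, cis, ts, trans.
#' @slot modes list of \code{list(weights, sigma)}: unit-norm per-residue
#'   weight vector and mode amplitude (angstrom).
#' @slot noise per-residue x per-state isotropic noise sigma (angstrom);
#'   columns named by state.
#' @slot hotspot integer interval (start, end) of elevated amplitude, or
#'   integer(0) for none.
#' @slot hotspotFactor amplitude multiplier inside the hotspot.
#' @slot rho fraction of amplitude-profile variance shared across
#'   isoforms, in [0, 1].
#' @slot profileSd log-scale SD of the Gaussian amplitude fields.
#' @slot baseNoise baseline noise sigma multiplying the amplitude profile
#'   in family generation (angstrom).
#' @slot seed master seed; per-isoform / per-state streams are derived
#'   deterministically from it.
#' @exportClass FamilySpec
setClass("FamilySpec",
  representation(
    nIsoforms = "integer",
    nResidues = "integer",
    nFrames = "integer",
    states = "character",
    modes = "list",
    noise = "matrix",
    hotspot = "integer",
    hotspotFactor = "numeric",
    rho = "numeric",
    profileSd = "numeric",
    baseNoise = "numeric",
    seed = "integer"
  )
)

setValidity("FamilySpec", function(object) {
  if (object@nResidues < 2L) return("at least two residues are required")
  if (object@nFrames < 2L) return("at least two frames are required")
  if (!length(object@states) || !all(object@states %in% .validStates))
    return("states must be a non-empty subset of free, cis, ts, trans")
  if (any(object@noise < 0)) return("noise sigmas must be non-negative")
  if (nrow(object@noise) != object@nResidues ||
      !identical(colnames(object@noise), object@states))
    return("noise must be an nResidues x states matrix with state colnames")
  for (m in object@modes) {
    if (!all(c("weights", "sigma") %in% names(m)))
      return("each mode needs weights and sigma")
    if (length(m$weights) != object@nResidues)
      return("mode weight vectors must have one weight per residue")
    if (abs(sqrt(sum(m$weights^2)) - 1) > 1e-8)
      return("mode weight vectors must have unit Euclidean norm")
    if (m$sigma < 0) return("mode sigma must be non-negative")
  }
  if (length(object@hotspot)) {
    if (length(object@hotspot) != 2L ||
        object@hotspot[1] > object@hotspot[2] ||
        object@hotspot[1] < 1L || object@hotspot[2] > object@nResidues)
      return("hotspot must be an interval within [1, nResidues]")
  }
  if (object@rho < 0 || object@rho > 1) return("rho must lie in [0, 1]")
  if (object@hotspotFactor < 0) return("hotspotFactor must be non-negative")
  TRUE
})

#' EnergySpec: parameters of a synthetic binding-energy series
#'
#' Stationary AR(1) model of per-frame binding free energies with
#' state-specific means, emulating the weak frame-to-frame correlation of
#' per-frame MM-PBSA output.
#'
#' @slot means,sds named per-state stationary mean and SD, kcal/mol.
#' @slot phi AR(1) coefficient, |phi| < 1.
#' @slot nSamples series length.
#' @slot seed master seed.
#' @exportClass EnergySpec
setClass("EnergySpec",
  representation(
    means = "numeric",
    sds = "numeric",
    phi = "numeric",
    nSamples = "integer",
    seed = "integer"
  )
)

setValidity("EnergySpec", function(object) {
  if (is.null(names(object@means)) ||
      !all(names(object@means) %in% c("cis", "ts", "trans")))
    return("means must be named by state (cis, ts, trans)")
  if (!identical(names(object@means), names(object@sds)))
    return("means and sds must be named identically")
  if (any(object@sds < 0)) return("standard deviations must be non-negative")
  if (abs(object@phi) >= 1) return("AR(1) coefficient must satisfy |phi| < 1")
  if (object@nSamples < 2L) return("at least two samples are required")
  TRUE
})
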