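## Synthetic ensemble generators.  These emulate, at desk scale, the
## ingredients of a comparative MD study of homologous enzymes: Gaussian
## collective-mode fluctuations about a fixed backbone reference,
## per-residue noise amplitudes with an optional shared hotspot, families
## of isoforms whose amplitude profiles share a tunable fraction rho of
## their variance, wrapped-normal dihedral series, and autocorrelated
## per-frame binding-energy series.  Everything is deterministic under a
## single master seed.

## Ideal backbone geometry (single published ideal set); omega frozen at
## 180 degrees for chain building -- only relative dihedral changes
## matter downstream.
.idealGeom <- list(
  bNCA = 1.458, bCAC = 1.525, bCN = 1.329, bCO = 1.231,
  bCACB = 1.530, bCBCG = 1.520,
  aCNCA = 121.7, aNCAC = 111.2, aCACN = 116.2, aCACO = 120.8,
  aNCACB = 110.5, aCACBCG = 114.0,
  tauCB = 122.6   # torsion C-N-CA-CB fixing the CB branch
)

## One master seed expands into independent deterministic streams.
## Stream ids stay small; the product stays far below 2^53 so the
## arithmetic is exact in doubles.
.subSeed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483647) * 1009 + as.numeric(stream) * 9973
  as.integer(s %% 2147483647)
}

#' Construct a synthetic-family specification
#'
#' @param nIsoforms number of isoforms in the family.
#' @param nResidues chain length.
#' @param states functional states to generate, subset of
#'   \code{c("free","cis","ts","trans")}.
#' @param nFrames frames per state ensemble.
#' @param modes list of planted collective modes, each
#'   \code{list(weights, sigma)} with a unit-norm per-residue weight
#'   vector and an amplitude sigma in angstrom.
#' @param noise per-residue x per-state isotropic noise sigma (angstrom);
#'   defaults to a constant \code{baseNoise} everywhere.
#' @param hotspot residue interval \code{c(start, end)} of elevated
#'   amplitude shared by all isoforms, or \code{NULL}.
#' @param hotspotFactor amplitude multiplier inside the hotspot.
#' @param rho fraction of amplitude-profile variance shared across
#'   isoforms, in [0, 1].
#' @param profileSd log-scale SD of the Gaussian amplitude fields
#'   (amplitudes are exponentiated, so they stay positive and the
#'   planted correlation is not distorted by truncation).
#' @param baseNoise baseline noise sigma in angstrom.
#' @param seed master seed.
#' @return a validated [FamilySpec-class].
#' @export
familySpec <- function(nIsoforms = 5L, nResidues = 160L,
                       states = c("free", "cis", "ts"),
                       nFrames = 500L, modes = list(), noise = NULL,
                       hotspot = NULL, hotspotFactor = 3,
                       rho = 0.5, profileSd = 0.25, baseNoise = 0.3,
                       seed = 1L) {
  states <- as.character(states)
  if (is.null(noise))
    noise <- matrix(baseNoise, nResidues, length(states))
  if (is.null(dim(noise)))
    noise <- matrix(noise, nResidues, length(states))
  colnames(noise) <- states
  new("FamilySpec",
      nIsoforms = as.integer(nIsoforms), nResidues = as.integer(nResidues),
      nFrames = as.integer(nFrames), states = states, modes = modes,
      noise = noise,
      hotspot = if (is.null(hotspot)) integer(0) else as.integer(hotspot),
      hotspotFactor = as.numeric(hotspotFactor), rho = as.numeric(rho),
      profileSd = as.numeric(profileSd), baseNoise = as.numeric(baseNoise),
      seed = as.integer(seed))
}

#' Construct a synthetic binding-energy specification
#'
#' @param means,sds named per-state stationary means and SDs (kcal/mol);
#'   names from \code{c("cis","ts","trans")}.
#' @param phi AR(1) coefficient, |phi| < 1.
#' @param nSamples series length.
#' @param seed master seed.
#' @export
energySpec <- function(means, sds = 2, phi = 0.3, nSamples = 1000L,
                       seed = 1L) {
  if (length(sds) == 1L) sds <- setNames(rep(sds, length(means)), names(means))
  new("EnergySpec", means = means, sds = sds[names(means)],
      phi = as.numeric(phi), nSamples = as.integer(nSamples),
      seed = as.integer(seed))
}

#' Build a single-frame backbone from phi/psi dihedrals
#'
#' Places N, CA, C, O atoms for every residue by sequential
#' internal-coordinate construction with ideal bond lengths and angles
#' and the peptide omega torsion frozen at 180 degrees.  Recomputing
#' phi/psi from the returned coordinates reproduces the inputs, which
#' makes the builder the round-trip oracle for dihedral extraction.
#'
#' @param phi,psi numeric vectors of length \code{n} (degrees in
#'   (-180, 180]).  \code{phi[1]} and \code{psi[n]} are undefined for a
#'   chain and are ignored (may be NA).
#' @param chi1 optional numeric vector of length \code{n}; where finite,
#'   a CB and CG atom are placed with ideal geometry so that the
#'   N-CA-CB-CG torsion equals the requested chi1.
#' @param isoform,state labels stored on the result.
#' @return a single-frame [BackboneEnsemble-class].
#' @export
buildBackbone <- function(phi, psi, chi1 = NULL,
                          isoform = "synthetic", state = "free") {
  n <- length(phi)
  if (length(psi) != n)
    stop("phi and psi must have one entry per residue")
  if (n < 2L) stop("at least two residues are required")
  checkAngle <- function(x, i, what) {
    if (!is.finite(x))
      stop(sprintf("non-finite %s angle for residue %d", what, i))
    if (x <= -180 - 1e-9 || x > 180 + 1e-9)
      stop(sprintf("%s angle for residue %d outside (-180, 180]", what, i))
    x
  }
  for (i in seq_len(n)) {
    if (i > 1L) checkAngle(phi[i], i, "phi")
    if (i < n) checkAngle(psi[i], i, "psi")
    if (!is.null(chi1) && !is.na(chi1[i])) checkAngle(chi1[i], i, "chi1")
  }
  g <- .idealGeom
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$bNCA, 0, 0)
  th <- .deg2rad(g$aNCAC)
  C[1, ] <- CA[1, ] + g$bCAC * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    if (i < n) {
      N[i + 1, ] <- .placeAtom(N[i, ], CA[i, ], C[i, ],
                               g$bCN, g$aCACN, psi[i])
      CA[i + 1, ] <- .placeAtom(CA[i, ], C[i, ], N[i + 1, ],
                                g$bNCA, g$aCNCA, 180)
      C[i + 1, ] <- .placeAtom(C[i, ], N[i + 1, ], CA[i + 1, ],
                               g$bCAC, g$aNCAC, phi[i + 1])
      ## carbonyl O anti to the next amide N
      O[i, ] <- .placeAtom(N[i, ], CA[i, ], C[i, ],
                           g$bCO, g$aCACO, .wrapAngle(psi[i] + 180))
    } else {
      O[i, ] <- .placeAtom(N[i, ], CA[i, ], C[i, ], g$bCO, g$aCACO, 180)
    }
  }
  atoms <- list(); xyz <- list()
  for (i in seq_len(n)) {
    side <- !is.null(chi1) && !is.na(chi1[i])
    nm <- c("N", "CA", "C", "O")
    pts <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    if (side) {
      CB <- .placeAtom(C[i, ], N[i, ], CA[i, ], g$bCACB, g$aNCACB, g$tauCB)
      CG <- .placeAtom(N[i, ], CA[i, ], CB, g$bCBCG, g$aCACBCG, chi1[i])
      nm <- c(nm, "CB", "CG")
      pts <- rbind(pts, CB, CG)
    }
    atoms[[i]] <- data.frame(resno = i,
                             resname = if (side) "LYS" else "GLY",
                             atom = nm)
    xyz[[i]] <- pts
  }
  at <- do.call(rbind, atoms)
  X <- do.call(rbind, xyz)
  arr <- array(NA_real_, c(1L, nrow(X), 3L))
  arr[1, , ] <- X
  new("BackboneEnsemble", coords = arr, atoms = at,
      isoform = isoform, state = state)
}

## Flattened coordinate ordering used throughout: atom-major
## (atom1.x, atom1.y, atom1.z, atom2.x, ...).
.flattenFrames <- function(coords) {
  d <- dim(coords)
  matrix(aperm(coords, c(3, 2, 1)), nrow = d[1], byrow = TRUE)
}

.unflattenFrames <- function(X, natoms) {
  n <- nrow(X)
  aperm(array(t(X), c(3L, natoms, n)), c(3, 2, 1))
}

## Deterministic per-residue unit directions of planted mode k; the same
## direction drives all four backbone atoms of a residue.
.modeResidueDirections <- function(spec, k) {
  set.seed(.subSeed(spec@seed, 900L + k))
  u <- matrix(rnorm(spec@nResidues * 3L), ncol = 3L)
  u / sqrt(rowSums(u^2))
}

## Orthonormal basis of the rigid-body subspace (3 translations + 3
## infinitesimal rotations) at a reference structure, in flattened
## coordinates.
.rigidBasis <- function(ref) {
  n <- nrow(ref)
  ctr <- sweep(ref, 2, colMeans(ref))
  B <- matrix(0, 3L * n, 6L)
  for (ax in 1:3) B[seq(ax, by = 3L, length.out = n), ax] <- 1
  omegas <- diag(3)
  for (k in 1:3) {
    v <- t(apply(ctr, 1, function(p) c(
      omegas[k, 2] * p[3] - omegas[k, 3] * p[2],
      omegas[k, 3] * p[1] - omegas[k, 1] * p[3],
      omegas[k, 1] * p[2] - omegas[k, 2] * p[1])))
    B[, 3L + k] <- as.vector(t(v))
  }
  qr.Q(qr(B))
}

#' Flattened planted mode vectors
#'
#' Returns each planted collective mode of a [familySpec()] as a unit
#' vector in the flattened backbone-coordinate space used by
#' [cartesianPCA()] (atom-major x,y,z over N, CA, C, O of every
#' residue).  Modes are internal motions: the rigid-body (translation
#' and infinitesimal rotation) component at the reference structure is
#' projected out before normalization, so ensemble superposition leaves
#' the planted displacement field intact and PCA can recover it.
#'
#' @param spec a [FamilySpec-class].
#' @return list of numeric unit vectors of length 12 * nResidues.
#' @export
plantedModes <- function(spec) {
  if (!length(spec@modes)) return(list())
  ref <- .referenceBackbone(spec@nResidues, "ref", "free")
  bb <- ref@coords[1, , ]
  Q <- .rigidBasis(bb)
  lapply(seq_along(spec@modes), function(k) {
    u <- .modeResidueDirections(spec, k)
    w <- spec@modes[[k]]$weights
    m <- matrix(0, spec@nResidues * 4L, 3L)
    for (a in 1:4) m[seq(a, by = 4L, length.out = spec@nResidues), ] <- u * w
    v <- as.vector(t(m))
    ## Alternating projections onto {rigid-free} and {supported where
    ## the weights are}: a mode localized to a few residues stays
    ## localized yet carries no net translation/rotation, so
    ## superposition leaves it intact.  For full-support weights the
    ## support restriction is a no-op and this is a single projection.
    support <- rep(rep(w != 0, each = 4L), each = 3L)
    for (it in 1:200) {
      proj <- crossprod(Q, v)
      v <- v - Q %*% proj
      v[!support] <- 0
      if (sum(proj^2) < 1e-24) break
    }
    as.vector(v / sqrt(sum(v^2)))
  })
}

## Reference chain shared by all synthetic ensembles: a gently curved
## strand (phi = -120, psi = 130), self-avoiding at these lengths.
.referenceBackbone <- function(nResidues, isoform, state) {
  buildBackbone(phi = c(NA, rep(-120, nResidues - 1L)),
                psi = c(rep(130, nResidues - 1L), NA),
                isoform = isoform, state = state)
}

#' Generate a collective-mode ensemble for one isoform and state
#'
#' Each frame is \code{reference + sum_k a_k(t) sigma_k mode_k + noise}
#' with \code{a_k(t)} standard normal, mode_k the unit-norm flattened
#' mode of [plantedModes()], and independent isotropic per-atom Gaussian
#' noise with the residue- and state-specific sigma of the spec.
#' Identical seeds give bit-identical ensembles.
#'
#' @param spec a [FamilySpec-class].
#' @param isoform isoform index in \code{1:nIsoforms}.
#' @param state one of \code{spec} states.
#' @param noiseScale optional per-residue multiplier on the noise sigmas
#'   (used by [generateIsoformFamily()] to impose amplitude profiles).
#' @return a [BackboneEnsemble-class] with \code{nFrames} frames.
#' @export
generateModeEnsemble <- function(spec, isoform = 1L, state = spec@states[1],
                                 noiseScale = NULL) {
  validObject(spec)
  if (!state %in% spec@states)
    stop(sprintf("state %s is not part of the specification", state))
  if (spec@nFrames < 2L) stop("at least two frames are required")
  sIdx <- match(state, .validStates)
  ref <- .referenceBackbone(spec@nResidues,
                            isoform = paste0("iso", isoform), state = state)
  refFlat <- .flattenFrames(ref@coords)[1, ]
  natoms <- length(refFlat) / 3L
  modes <- plantedModes(spec)
  sigmaRes <- spec@noise[, state]
  if (!is.null(noiseScale)) sigmaRes <- sigmaRes * noiseScale
  sigmaAtom <- rep(sigmaRes, each = 4L)           # per atom
  sigmaCoord <- rep(sigmaAtom, each = 3L)         # per flattened coordinate
  set.seed(.subSeed(spec@seed, 1000L + isoform * 17L + sIdx))
  n <- spec@nFrames
  X <- matrix(refFlat, n, length(refFlat), byrow = TRUE)
  for (k in seq_along(modes)) {
    a <- rnorm(n) * spec@modes[[k]]$sigma
    X <- X + tcrossprod(a, modes[[k]])
  }
  if (any(sigmaCoord > 0)) {
    noise <- matrix(rnorm(n * length(refFlat)), n) *
      matrix(sigmaCoord, n, length(sigmaCoord), byrow = TRUE)
    X <- X + noise
  }
  new("BackboneEnsemble", coords = .unflattenFrames(X, natoms),
      atoms = ref@atoms, isoform = paste0("iso", isoform), state = state)
}

#' Generate a wrapped-normal dihedral time series
#'
#' Samples \code{N(mean, sigma^2)} and wraps into (-180, 180], so the
#' series crosses the periodic boundary whenever the mean sits near
#' +/-180 degrees.
#'
#' @param mean,sigma circular mean and scale, degrees.
#' @param n series length.
#' @param seed seed.
#' @param resno,type key under which the series is stored.
#' @return a [DihedralSeries-class] with a single entry.
#' @export
generateDihedralSeries <- function(mean, sigma, n, seed = 1L,
                                   resno = 1L, type = "phi") {
  if (sigma < 0) stop("sigma must be non-negative")
  set.seed(as.integer(seed))
  x <- .wrapAngle(rnorm(n, mean, sigma))
  new("DihedralSeries",
      values = matrix(x, ncol = 1),
      info = data.frame(resno = as.integer(resno), type = type),
      isoform = "synthetic", state = "free")
}

#' Generate an autocorrelated binding-energy series
#'
#' Stationary AR(1) process \code{x_t = mu + phi (x_{t-1} - mu) + eps_t}
#' with innovation variance \code{sigma^2 (1 - phi^2)}, so the
#' stationary mean and SD are exactly the specified per-state values.
#'
#' @param spec an [EnergySpec-class].
#' @param state state whose mean/SD to use.
#' @param label variant label stored on the series.
#' @return an [EnergySeries-class].
#' @export
generateEnergySeries <- function(spec, state, label = "synthetic") {
  validObject(spec)
  if (!state %in% names(spec@means))
    stop(sprintf("state %s has no mean in the specification", state))
  mu <- spec@means[[state]]
  sdv <- spec@sds[[state]]
  phi <- spec@phi
  n <- spec@nSamples
  set.seed(.subSeed(spec@seed, 5000L + match(state, c("cis", "ts", "trans"))))
  x <- numeric(n)
  x[1] <- rnorm(1, mu, sdv)
  if (n > 1L) {
    eps <- rnorm(n - 1L, 0, sdv * sqrt(1 - phi^2))
    for (t in 2:n) x[t] <- mu + phi * (x[t - 1] - mu) + eps[t - 1L]
  }
  new("EnergySeries", state = state, dG = x, index = seq_len(n),
      label = label)
}

## Per-isoform target amplitude profiles: exponentiated mixtures of a
## common and an isoform-specific standard-normal field, so a fraction
## rho of the log-amplitude variance is shared across isoforms.
.familyAmplitudes <- function(spec) {
  set.seed(.subSeed(spec@seed, 1L))
  common <- rnorm(spec@nResidues)
  amps <- vector("list", spec@nIsoforms)
  for (i in seq_len(spec@nIsoforms)) {
    set.seed(.subSeed(spec@seed, 100L + i))
    own <- rnorm(spec@nResidues)
    g <- sqrt(spec@rho) * common + sqrt(1 - spec@rho) * own
    a <- exp(spec@profileSd * g)
    if (length(spec@hotspot))
      a[spec@hotspot[1]:spec@hotspot[2]] <-
        a[spec@hotspot[1]:spec@hotspot[2]] * spec@hotspotFactor
    amps[[i]] <- a
  }
  amps
}

#' Generate a family of isoform ensembles with planted conservation
#'
#' Draws per-isoform target amplitude profiles
#' \code{sqrt(rho) * common + sqrt(1 - rho) * specific} on the log scale
#' (then exponentiated, so amplitudes stay positive without truncation),
#' multiplies in the shared hotspot block, and generates every requested
#' state ensemble with per-residue noise scaled by the isoform's
#' amplitude profile.  The ground-truth profiles are returned alongside
#' the ensembles so downstream recovery can be scored.
#'
#' @param spec a [FamilySpec-class].
#' @param profilesOnly skip ensemble generation and return only the
#'   ground-truth profiles (fast path for planted-statistics studies).
#' @return list with elements \code{profiles} (per isoform, a
#'   ground-truth [FlexibilityProfile-class] holding the expected RMSF
#'   \code{sigma * sqrt(3)} per residue) and \code{ensembles} (per
#'   isoform, a named list of per-state [BackboneEnsemble-class];
#'   \code{NULL} under \code{profilesOnly}).
#' @export
generateIsoformFamily <- function(spec, profilesOnly = FALSE) {
  validObject(spec)
  amps <- .familyAmplitudes(spec)
  meanNoise <- rowMeans(spec@noise)
  profiles <- vector("list", spec@nIsoforms)
  ensembles <- vector("list", spec@nIsoforms)
  for (i in seq_len(spec@nIsoforms)) {
    profiles[[i]] <- new("FlexibilityProfile", metric = "rmsf",
                         values = amps[[i]] * meanNoise * sqrt(3),
                         columns = seq_len(spec@nResidues),
                         isoform = paste0("iso", i), composition = "target")
    if (!profilesOnly) {
      ens <- lapply(spec@states, function(s)
        generateModeEnsemble(spec, isoform = i, state = s,
                             noiseScale = amps[[i]]))
      names(ens) <- spec@states
      ensembles[[i]] <- ens
    }
  }
  names(profiles) <- paste0("iso", seq_len(spec@nIsoforms))
  if (!profilesOnly)
    names(ensembles) <- paste0("iso", seq_len(spec@nIsoforms))
  list(profiles = profiles,
       ensembles = if (profilesOnly) NULL else ensembles)
}
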