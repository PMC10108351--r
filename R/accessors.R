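#' Accessors for BackboneEnsemble
#'
#' @param x a [BackboneEnsemble-class] object.
#' @return `nFrames`, `nAtoms`, `nResidues`: integer counts; `coords` the
#'   frames x atoms x 3 array; `atomRecords` the atom table;
#'   `meanStructure` the converged mean (atoms x 3) of a superposed
#'   ensemble.
#' @aliases nFrames nAtoms nResidues atomRecords coords isoformId
#'   stateLabel isSuperposed meanStructure
#' @name BackboneEnsemble-accessors
NULL

#' @rdname BackboneEnsemble-accessors
#' @export
setMethod("nFrames", "BackboneEnsemble", function(x) dim(x@coords)[1])

#' @rdname BackboneEnsemble-accessors
#' @export
setMethod("nAtoms", "BackboneEnsemble", function(x) dim(x@coords)[2])

#' @rdname BackboneEnsemble-accessors
#' @export
setMethod("nResidues", "BackboneEnsemble",
          function(x) length(unique(x@atoms$resno)))

#' @rdname BackboneEnsemble-accessors
#' @export
setMethod("atomRecords", "BackboneEnsemble", function(x) x@atoms)

#' @rdname BackboneEnsemble-accessors
#' @export
setMethod("coords", "BackboneEnsemble", function(x) x@coords)

#' @rdname BackboneEnsemble-accessors
#' @export
setMethod("isoformId", "BackboneEnsemble", function(x) x@isoform)

#' @rdname BackboneEnsemble-accessors
#' @export
setMethod("stateLabel", "BackboneEnsemble", function(x) x@state)

#' @rdname BackboneEnsemble-accessors
#' @export
setMethod("isSuperposed", "BackboneEnsemble", function(x) x@superposed)

#' @rdname BackboneEnsemble-accessors
#' @export
setMethod("meanStructure", "BackboneEnsemble", function(x) {
  if (!x@superposed)
    stop("ensemble has not been superposed; call superposeEnsemble() first")
  x@refMean
})

#' @export
setMethod("nFrames", "DihedralSeries", function(x) nrow(x@values))

#' @export
setMethod("isoformId", "DihedralSeries", function(x) x@isoform)

#' @export
setMethod("stateLabel", "DihedralSeries", function(x) x@state)

#' Dihedral angle matrix and key
#'
#' `dihedralValues` returns the frames x dihedrals angle matrix
#' (degrees); `dihedralInfo` the parallel (resno, type) key.
#'
#' @param x a [DihedralSeries-class].
#' @export
dihedralValues <- function(x) {
  stopifnot(is(x, "DihedralSeries"))
  x@values
}

#' @rdname dihedralValues
#' @export
dihedralInfo <- function(x) {
  stopifnot(is(x, "DihedralSeries"))
  x@info
}

#' @export
setMethod("universalColumns", "AlignmentMap", function(x) x@universal)

#' Alignment column of each residue of an isoform
#'
#' @param x an [AlignmentMap-class].
#' @param isoform isoform id present in the map.
#' @return integer vector: alignment column per residue.
#' @export
setMethod("residueColumn", "AlignmentMap", function(x, isoform) {
  if (!isoform %in% names(x@maps))
    stop(sprintf("isoform %s not present in the alignment map", isoform))
  x@maps[[isoform]]
})

#' @export
setMethod("profileValues", "FlexibilityProfile", function(x) x@values)

#' @export
setMethod("profileColumns", "FlexibilityProfile", function(x) x@columns)

#' @export
setMethod("metricLabel", "FlexibilityProfile", function(x) x@metric)

#' @export
setMethod("isoformId", "FlexibilityProfile", function(x) x@isoform)

#' @export
setMethod("stateLabel", "FlexibilityProfile", function(x) x@composition)

#' @export
setMethod("eigenValues", "PCAModel", function(x) x@values)

#' @export
setMethod("eigenVectors", "PCAModel", function(x) x@vectors)

#' @export
setMethod("scores", "PCAModel", function(x) x@scores)

#' @export
setMethod("scoreGroups", "PCAModel", function(x) x@scoreGroups)

#' @export
setMethod("varianceFraction", "PCAModel", function(x) x@varFraction)

#' @export
setMethod("coordinateLabels", "PCAModel", function(x) x@labels)

#' @export
setMethod("correlations", "ConservationMatrix", function(x) x@r)

#' @export
setMethod("meanCorrelation", "ConservationMatrix", function(x) x@meanR)

#' @export
setMethod("keyRegions", "KeyRegionReport", function(x) x@regions)

#' @export
setMethod("consensusScore", "KeyRegionReport", function(x)
  setNames(x@score, x@columns))

#' @export
setMethod("energyValues", "EnergySeries", function(x) x@dG)

#' @export
setMethod("stateLabel", "EnergySeries", function(x) x@state)

#' @export
setMethod("verdict", "CatalysisReport", function(x) x@verdict)

#' @export
setMethod("stateMeans", "CatalysisReport", function(x) x@means)
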