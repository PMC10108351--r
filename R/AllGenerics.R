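#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @export
setGeneric("atomRecords", function(x) standardGeneric("atomRecords"))

#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @export
setGeneric("isoformId", function(x) standardGeneric("isoformId"))

#' @export
setGeneric("stateLabel", function(x) standardGeneric("stateLabel"))

#' @export
setGeneric("isSuperposed", function(x) standardGeneric("isSuperposed"))

#' @export
setGeneric("meanStructure", function(x) standardGeneric("meanStructure"))

#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @export
setGeneric("profileColumns", function(x) standardGeneric("profileColumns"))

#' @export
setGeneric("metricLabel", function(x) standardGeneric("metricLabel"))

#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))

#' @export
setGeneric("eigenVectors", function(x) standardGeneric("eigenVectors"))

#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @export
setGeneric("scoreGroups", function(x) standardGeneric("scoreGroups"))

#' @export
setGeneric("varianceFraction", function(x) standardGeneric("varianceFraction"))

#' @export
setGeneric("coordinateLabels", function(x) standardGeneric("coordinateLabels"))

#' @export
setGeneric("correlations", function(x) standardGeneric("correlations"))

#' @export
setGeneric("meanCorrelation", function(x) standardGeneric("meanCorrelation"))

#' @export
setGeneric("keyRegions", function(x) standardGeneric("keyRegions"))

#' @export
setGeneric("consensusScore", function(x) standardGeneric("consensusScore"))

#' @export
setGeneric("energyValues", function(x) standardGeneric("energyValues"))

#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' @export
setGeneric("stateMeans", function(x) standardGeneric("stateMeans"))

#' @export
setGeneric("universalColumns", function(x) standardGeneric("universalColumns"))

#' @export
setGeneric("residueColumn", function(x, isoform) standardGeneric("residueColumn"))
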