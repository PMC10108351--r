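#' @importFrom grDevices chull
#' @importFrom graphics hist
NULL

setMethod("show", "BackboneEnsemble", function(object) {
  cat(sprintf("BackboneEnsemble: %s [%s]\n", object@isoform, object@state))
  cat(sprintf("  %d frame(s), %d atoms, %d residues%s\n",
              nFrames(object), nAtoms(object), nResidues(object),
              if (object@superposed) ", superposed" else ""))
})

setMethod("show", "DihedralSeries", function(object) {
  tt <- table(object@info$type)
  cat(sprintf("DihedralSeries: %s [%s]\n", object@isoform, object@state))
  cat(sprintf("  %d frame(s); %s\n", nrow(object@values),
              paste(sprintf("%s x %d", names(tt), as.integer(tt)),
                    collapse = ", ")))
})

setMethod("show", "AlignmentMap", function(object) {
  cat(sprintf("AlignmentMap: %d isoform(s), width %d, %d universal column(s)\n",
              length(object@maps), object@width, length(object@universal)))
})

setMethod("show", "FlexibilityProfile", function(object) {
  unit <- switch(object@metric, rmsf = "A", angvar = "deg^2",
                 contribution = "fraction")
  cat(sprintf("FlexibilityProfile (%s, %s): %s [%s], %d position(s)\n",
              object@metric, unit, object@isoform, object@composition,
              length(object@values)))
})

setMethod("show", "PCAModel", function(object) {
  cat(sprintf("PCAModel (%s): %d coordinates, %d frames projected\n",
              object@space, nrow(object@vectors), nrow(object@scores)))
  k <- min(3L, length(object@varFraction))
  cat(sprintf("  var fraction PC1..PC%d: %s\n", k,
              paste(sprintf("%.3f", object@varFraction[seq_len(k)]),
                    collapse = ", ")))
})

setMethod("show", "ConservationMatrix", function(object) {
  cat(sprintf("ConservationMatrix (%s, %s): %d isoforms, mean off-diagonal r = %.3f\n",
              object@metric, object@composition, nrow(object@r),
              object@meanR))
})

setMethod("show", "KeyRegionReport", function(object) {
  cat(sprintf("KeyRegionReport: z = %.2f, consensus >= %.2f\n",
              object@zThreshold, object@consensusMin))
  if (nrow(object@regions)) {
    cat("  regions:",
        paste(sprintf("[%d, %d]", object@regions$start,
                      object@regions$end), collapse = ", "), "\n")
  } else cat("  no consensus regions\n")
})

setMethod("show", "EnergySeries", function(object) {
  cat(sprintf("EnergySeries: %s (%s), %d samples, mean %.2f kcal/mol\n",
              object@label, object@state, length(object@dG),
              mean(object@dG)))
})

setMethod("show", "CatalysisReport", function(object) {
  cat(sprintf("CatalysisReport: %s -> %s\n", object@label, object@verdict))
  cat(sprintf("  mean dG (kcal/mol): cis %.2f, ts %.2f, trans %.2f\n",
              object@means["cis"], object@means["ts"],
              object@means["trans"]))
  cat(sprintf("  barrier changes: delta_cis %.2f +/- %.2f, delta_trans %.2f +/- %.2f\n",
              object@deltaCis, object@deltaCisSE, object@deltaTrans,
              object@deltaTransSE))
})

setMethod("show", "FamilySpec", function(object) {
  cat(sprintf("FamilySpec: %d isoforms x %d residues, states %s, %d frames, rho %.2f, seed %d\n",
              object@nIsoforms, object@nResidues,
              paste(object@states, collapse = "/"), object@nFrames,
              object@rho, object@seed))
})

setMethod("show", "EnergySpec", function(object) {
  cat(sprintf("EnergySpec: states %s, AR(1) phi %.2f, n %d, seed %d\n",
              paste(sprintf("%s %.2f", names(object@means), object@means),
                    collapse = ", "),
              object@phi, object@nSamples, object@seed))
})
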