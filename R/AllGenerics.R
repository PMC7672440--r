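#' @rdname MotifPWM-class
#' @param object,x a package object.
#' @export
setGeneric("tfId", function(object) standardGeneric("tfId"))
#' @rdname MotifPWM-class
#' @export
setGeneric("pwmProbs", function(object) standardGeneric("pwmProbs"))
#' @rdname MotifPWM-class
#' @export
setGeneric("pwmBackground",
           function(object) standardGeneric("pwmBackground"))
#' @rdname MotifPWM-class
#' @export
setGeneric("motifLength", function(object) standardGeneric("motifLength"))
#' @rdname MotifPWM-class
#' @export
setGeneric("consensusSeq", function(object) standardGeneric("consensusSeq"))

#' @rdname GeneAnnotationSet-class
#' @export
setGeneric("geneTable", function(object) standardGeneric("geneTable"))
#' @rdname GeneAnnotationSet-class
#' @export
setGeneric("isoformTable", function(object) standardGeneric("isoformTable"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureInfo", function(object) standardGeneric("featureInfo"))
#' @rdname FeatureMatrix-class
#' @export
setGeneric("pairInfo", function(object) standardGeneric("pairInfo"))
#' @rdname FeatureMatrix-class
#' @export
setGeneric("imputedMask", function(object) standardGeneric("imputedMask"))

#' @rdname CVResult-class
#' @export
setGeneric("cvAucs", function(object) standardGeneric("cvAucs"))
#' @rdname CVResult-class
#' @export
setGeneric("cvImportance", function(object) standardGeneric("cvImportance"))
#' @rdname CVResult-class
#' @export
setGeneric("cvInteractions",
           function(object) standardGeneric("cvInteractions"))
#' @rdname CVResult-class
#' @export
setGeneric("cvBaseline", function(object) standardGeneric("cvBaseline"))

#' @rdname GroundTruth-class
#' @export
setGeneric("coupledPairs", function(object) standardGeneric("coupledPairs"))
#' @rdname GroundTruth-class
#' @export
setGeneric("plantedHits", function(object) standardGeneric("plantedHits"))
#' @rdname GroundTruth-class
#' @export
setGeneric("expectedPairR", function(object) standardGeneric("expectedPairR"))
#' @rdname GroundTruth-class
#' @export
setGeneric("informativeFeatures",
           function(object) standardGeneric("informativeFeatures"))

setMethod("tfId", "MotifPWM", function(object) object@tfId)
setMethod("pwmProbs", "MotifPWM", function(object) object@probs)
setMethod("pwmBackground", "MotifPWM", function(object) object@background)
setMethod("motifLength", "MotifPWM", function(object) nrow(object@probs))
setMethod("consensusSeq", "MotifPWM", function(object) {
  paste(DNA_BASES[max.col(object@probs, ties.method = "first")],
        collapse = "")
})
setMethod("show", "MotifPWM", function(object) {
  cat("MotifPWM for", object@tfId, "- length", motifLength(object),
      "bp, consensus", consensusSeq(object), "\n")
})

setMethod("geneTable", "GeneAnnotationSet", function(object) object@genes)
setMethod("isoformTable", "GeneAnnotationSet",
          function(object) object@isoforms)
setMethod("show", "GeneAnnotationSet", function(object) {
  cat("GeneAnnotationSet:", nrow(object@genes), "genes (",
      sum(object@genes$is_tf), "TFs ),", nrow(object@isoforms),
      "isoforms\n")
})

setMethod("featureValues", "FeatureMatrix", function(object) object@values)
setMethod("featureInfo", "FeatureMatrix", function(object) object@featureInfo)
setMethod("pairInfo", "FeatureMatrix", function(object) object@pairInfo)
setMethod("imputedMask", "FeatureMatrix", function(object) object@imputed)
setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", nrow(object@values), "pairs x",
      ncol(object@values), "features;",
      sum(object@imputed), "imputed cells\n")
  print(table(object@featureInfo$category))
})

setMethod("cvAucs", "CVResult", function(object) object@aucs)
setMethod("cvImportance", "CVResult", function(object) object@mda)
setMethod("cvInteractions", "CVResult", function(object) object@interactions)
setMethod("cvBaseline", "CVResult", function(object) object@baseline)
setMethod("show", "CVResult", function(object) {
  cat("CVResult over", nrow(object@aucs), "repeats: median ROC-AUC",
      round(median(object@aucs$roc_auc), 3), ", median PR-AUC",
      round(median(object@aucs$pr_auc), 3), "\n")
  if (nrow(object@baseline))
    cat("  permuted-label baseline: median ROC-AUC",
        round(median(object@baseline$roc_auc), 3), "\n")
})

setMethod("coupledPairs", "GroundTruth", function(object) object@coupledPairs)
setMethod("plantedHits", "GroundTruth", function(object) object@plantedHits)
setMethod("expectedPairR", "GroundTruth",
          function(object) object@expectedPairR)
setMethod("informativeFeatures", "GroundTruth",
          function(object) object@informativeFeatures)
setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@plantedHits), "planted hits,",
      nrow(object@coupledPairs), "coupled pairs,",
      length(object@informativeFeatures), "shifted features\n")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nTF, "TFs,", object@nGene, "genes,",
      object@nSample, "samples; beta =", object@couplingBeta,
      ", sigma =", object@noiseSd, ", seed =", object@seed, "\n")
})
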