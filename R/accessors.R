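## Generics, accessors and show methods.

#' @rdname ModuleLibrary-class
#' @param object,x a ModuleLibrary.
#' @export
setGeneric("moduleRegion", function(x) standardGeneric("moduleRegion"))
#' @rdname ModuleLibrary-class
#' @export
setMethod("moduleRegion", "ModuleLibrary", function(x) x@region)

#' @rdname ModuleLibrary-class
#' @export
setGeneric("moduleIds", function(x) standardGeneric("moduleIds"))
#' @rdname ModuleLibrary-class
#' @export
setMethod("moduleIds", "ModuleLibrary",
          function(x) as.character(x@modules$module_id))

#' @rdname ModuleLibrary-class
#' @export
setGeneric("moduleResidues", function(x) standardGeneric("moduleResidues"))
#' @rdname ModuleLibrary-class
#' @export
setMethod("moduleResidues", "ModuleLibrary", function(x) x@modules)

#' @rdname ModuleLibrary-class
#' @param latent return the noise-free latent compatibilities instead of the
#'   measured activities.
#' @export
setGeneric("moduleActivities",
           function(x, latent = FALSE) standardGeneric("moduleActivities"))
#' @rdname ModuleLibrary-class
#' @export
setMethod("moduleActivities", "ModuleLibrary", function(x, latent = FALSE) {
  if (latent) {
    if (is.null(x@latent)) stop("library has no latent compatibilities")
    x@latent
  } else x@activities
})

setMethod("show", "ModuleLibrary", function(object) {
  cat("ModuleLibrary(", object@region, "): ",
      nrow(object@modules), " modules x ",
      ncol(object@activities), " region targets\n", sep = "")
  cat("  measured activity range: ",
      paste(sprintf("%.3f", range(object@activities)), collapse = " .. "),
      "\n", sep = "")
})

#' @rdname CombinatorialPool-class
#' @param x a CombinatorialPool.
#' @export
setGeneric("poolTarget", function(x) standardGeneric("poolTarget"))
#' @rdname CombinatorialPool-class
#' @export
setMethod("poolTarget", "CombinatorialPool", function(x) x@target)

#' @rdname CombinatorialPool-class
#' @export
setGeneric("poolCandidates", function(x) standardGeneric("poolCandidates"))
#' @rdname CombinatorialPool-class
#' @export
setMethod("poolCandidates", "CombinatorialPool", function(x) x@candidates)

#' @rdname CombinatorialPool-class
#' @export
setGeneric("poolPositives", function(x) standardGeneric("poolPositives"))
#' @rdname CombinatorialPool-class
#' @export
setMethod("poolPositives", "CombinatorialPool", function(x) x@positives)

setMethod("show", "CombinatorialPool", function(object) {
  cat("CombinatorialPool on ", object@target, "\n",
      "  ", nrow(object@candidates), " distinct candidates, ",
      nrow(object@positives), " sequenced positives\n", sep = "")
})

#' @rdname ScreeningSet-class
#' @param x,object a ScreeningSet.
#' @export
setGeneric("screeningRecords", function(x) standardGeneric("screeningRecords"))
#' @rdname ScreeningSet-class
#' @export
setMethod("screeningRecords", "ScreeningSet", function(x) x@records)

#' @rdname ScreeningSet-class
#' @export
setGeneric("screeningTargets", function(x) standardGeneric("screeningTargets"))
#' @rdname ScreeningSet-class
#' @export
setMethod("screeningTargets", "ScreeningSet", function(x) x@targets)

setMethod("show", "ScreeningSet", function(object) {
  r <- object@records
  pos <- tapply(r$label, r$target, sum)
  size <- tapply(r$label, r$target, length)
  cat("ScreeningSet: ", length(object@targets), " targets, ",
      nrow(r), " records\n",
      "  mean pool size ", round(mean(size)), ", mean positives/target ",
      sprintf("%.1f", mean(pos)), "\n", sep = "")
})

#' @rdname FeatureMatrix-class
#' @param x,object a FeatureMatrix.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname FeatureMatrix-class
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@x)

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureColumns", function(x) standardGeneric("featureColumns"))
#' @rdname FeatureMatrix-class
#' @export
setMethod("featureColumns", "FeatureMatrix", function(x) x@columnData)

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureEncoding", function(x) standardGeneric("featureEncoding"))
#' @rdname FeatureMatrix-class
#' @export
setMethod("featureEncoding", "FeatureMatrix", function(x) x@encoding)

setMethod("show", "FeatureMatrix", function(object) {
  cd <- object@columnData
  cat("FeatureMatrix [", object@encoding, "]: ",
      length(object@rowTarget), " rows x ", nrow(cd), " columns (",
      sum(cd$order == 1L), " order-1, ", sum(cd$order == 2L),
      " order-2)\n", sep = "")
})

#' @rdname TrainedScorer-class
#' @param x,object a TrainedScorer.
#' @export
setGeneric("scorerKind", function(x) standardGeneric("scorerKind"))
#' @rdname TrainedScorer-class
#' @export
setMethod("scorerKind", "TrainedScorer", function(x) x@kind)

#' @rdname TrainedScorer-class
#' @export
setGeneric("scorerGroup", function(x) standardGeneric("scorerGroup"))
#' @rdname TrainedScorer-class
#' @export
setMethod("scorerGroup", "TrainedScorer", function(x) x@featureGroup)

#' @rdname TrainedScorer-class
#' @export
setGeneric("innerCVRecord", function(x) standardGeneric("innerCVRecord"))
#' @rdname TrainedScorer-class
#' @export
setMethod("innerCVRecord", "TrainedScorer", function(x) x@innerCV)

setMethod("show", "TrainedScorer", function(object) {
  cat("TrainedScorer<", object@kind, "> on group ", object@featureGroup,
      "\n", sep = "")
  if (object@kind == "ensemble")
    cat("  members:", paste(vapply(object@fit, scorerKind, ""),
                            collapse = " + "),
        "| combine:", object@combine, "\n")
})

#' @rdname CVSummary-class
#' @param x,object a CVSummary.
#' @export
setGeneric("cvPerTarget", function(x) standardGeneric("cvPerTarget"))
#' @rdname CVSummary-class
#' @export
setMethod("cvPerTarget", "CVSummary", function(x) x@perTarget)

#' @rdname CVSummary-class
#' @export
setGeneric("cvAggregates", function(x) standardGeneric("cvAggregates"))
#' @rdname CVSummary-class
#' @export
setMethod("cvAggregates", "CVSummary", function(x) x@aggregates)

setMethod("show", "CVSummary", function(object) {
  a <- object@aggregates
  cat("CVSummary: ", object@settings$replicates, " replicates, group ",
      object@settings$featureGroup, "\n",
      sprintf("  mean AUC %.3f (SE %.3f) | mean Top%d %.2f | %%Top%d %.1f%%\n",
              a$mean_auc, a$se_auc, object@settings$N, a$mean_topN,
              object@settings$N, 100 * a$pct_topN), sep = "")
})
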