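#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname accessors
setMethod("subjectId", "GaitRecording", function(object) object@subjectId)
#' @rdname accessors
setMethod("samplingRate", "GaitRecording", function(object) object@samplingRate)
#' @rdname accessors
setMethod("accelMatrix", "GaitRecording", function(object) object@accel)
#' @rdname accessors
setMethod("timePoints", "GaitRecording", function(object) object@time)

#' @rdname accessors
setMethod("intervals", "ActivityTrack", function(object) object@intervals)

#' @rdname accessors
setMethod("subjectId", "GaitWindows", function(object) object@subjectId)
#' @rdname accessors
setMethod("samplingRate", "GaitWindows", function(object) object@samplingRate)
#' @rdname accessors
setMethod("windowStarts", "GaitWindows", function(object) object@windowStarts)
#' @rdname accessors
setMethod("windowActivities", "GaitWindows", function(object) object@activities)

#' @rdname accessors
setMethod("subjectId", "GaitFeatureSet", function(object)
  S4Vectors::metadata(object)$subjectId)
#' @rdname accessors
setMethod("windowStarts", "GaitFeatureSet", function(object)
  SummarizedExperiment::colData(object)$windowStart)
#' @rdname accessors
setMethod("windowActivities", "GaitFeatureSet", function(object)
  SummarizedExperiment::colData(object)$activity)

#' @describeIn accessors windows-by-features matrix (transpose of the
#'   stored assay, which is features-by-windows).
setMethod("featureMatrix", "GaitFeatureSet", function(object)
  t(SummarizedExperiment::assay(object, "features")))

#' @rdname accessors
setMethod("embeddingCoords", "TsneMap", function(object) object@coords)
#' @rdname accessors
setMethod("tsneSeed", "TsneMap", function(object) object@seed)
#' @rdname accessors
setMethod("tsneParams", "TsneMap", function(object) object@params)
#' @rdname accessors
setMethod("windowActivities", "TsneMap", function(object)
  object@windowInfo$activity)

#' @rdname accessors
setMethod("clusterIds", "DbscanClustering", function(object) object@clusterId)
#' @rdname accessors
setMethod("isOutlier", "DbscanClustering", function(object)
  object@clusterId == 0L)
#' @rdname accessors
setMethod("nClusters", "DbscanClustering", function(object)
  max(object@clusterId, 0L))

#' @rdname accessors
setMethod("assignmentStatus", "StairAssignment", function(object) object@status)
#' @rdname accessors
setMethod("clusterSummaries", "StairAssignment", function(object) object@summaries)
#' @rdname accessors
setMethod("stairClusterId", "StairAssignment", function(object) object@stairId)
#' @rdname accessors
setMethod("walkClusterIds", "StairAssignment", function(object) object@walkIds)
#' @rdname accessors
setMethod("finalLabels", "StairAssignment", function(object) object@finalLabels)

#' @rdname accessors
setMethod("perSeedResults", "StairEvalReport", function(object) object@perSeed)
#' @rdname accessors
setMethod("aggregateResults", "StairEvalReport", function(object) object@aggregate)

setMethod("show", "GaitRecording", function(object) {
  dur <- if (length(object@time)) diff(range(object@time)) else 0
  cat("GaitRecording for subject", object@subjectId, "\n")
  cat(sprintf("  %d samples at %g Hz (%.1f min), placement %s\n",
              nrow(object@accel), object@samplingRate, dur / 60,
              object@placement))
})

setMethod("show", "ActivityTrack", function(object) {
  iv <- object@intervals
  cat(sprintf("ActivityTrack with %d intervals\n", nrow(iv)))
  if (nrow(iv)) {
    tab <- tapply(iv$end - iv$start, iv$activity, sum)
    for (a in names(tab))
      cat(sprintf("  %-12s %.1f s\n", a, tab[[a]]))
  }
})

setMethod("show", "GaitWindows", function(object) {
  cat(sprintf("GaitWindows: %d windows of %g s (%d samples) for subject %s\n",
              dim(object@data)[1L], object@windowLen,
              dim(object@data)[2L], object@subjectId))
  print(table(object@activities))
})

setMethod("show", "GaitFeatureSet", function(object) {
  md <- S4Vectors::metadata(object)
  cat(sprintf("GaitFeatureSet: %d features x %d windows, subject %s\n",
              nrow(object), ncol(object),
              if (is.null(md$subjectId)) "?" else md$subjectId))
  cat("  standardized:", isTRUE(md$standardized), "\n")
  if (length(md$constantFeatures))
    cat("  constant features zeroed:", length(md$constantFeatures), "\n")
  callNextMethod()
})

setMethod("show", "TsneMap", function(object) {
  cat(sprintf("TsneMap: %d points, seed %d, perplexity %g, exaggeration %g\n",
              nrow(object@coords), object@seed,
              object@params$perplexity, object@params$exaggeration))
})

setMethod("show", "DbscanClustering", function(object) {
  k <- max(object@clusterId, 0L)
  cat(sprintf("DbscanClustering: %d clusters, %d outliers of %d points (eps %g, minPts %d)\n",
              k, sum(object@clusterId == 0L), length(object@clusterId),
              object@eps, object@minPts))
  if (k > 0L)
    print(table(factor(object@clusterId[object@clusterId > 0L],
                       levels = seq_len(k))))
})

setMethod("show", "StairAssignment", function(object) {
  cat("StairAssignment, status:", object@status, "\n")
  if (object@status == "ok") {
    cat(sprintf("  stair cluster: %d; walking clusters: %s\n",
                object@stairId, paste(object@walkIds, collapse = ", ")))
    cat(sprintf("  final labels: %d Walk, %d Stair, %d Outlier\n",
                sum(object@finalLabels == "Walk"),
                sum(object@finalLabels == "Stair"),
                sum(object@finalLabels == "Outlier")))
  } else {
    cat(sprintf("  DBSCAN found %d cluster(s); no stair assignment made\n",
                object@nClusters))
  }
})

setMethod("show", "StairEvalReport", function(object) {
  cat("StairEvalReport over", nrow(object@perSeed), "t-SNE seeds\n")
  print(object@perSeed, row.names = FALSE)
  ag <- object@aggregate
  if (!is.null(ag$meanPurity) && is.finite(ag$meanPurity))
    cat(sprintf("  mean purity %.3f (sd %.3f), NMI initial %.3f -> corrected %.3f\n",
                ag$meanPurity, ag$sdPurity, ag$meanNmiInitial,
                ag$meanNmiCorrected))
})
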