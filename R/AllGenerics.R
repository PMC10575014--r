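#' @include AllClasses.R
NULL

#' Accessors for stairclust classes
#'
#' Small accessor generics used across the pipeline classes; prefer these
#' over direct slot access.
#'
#' @param object a stairclust S4 object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("accelMatrix", function(object) standardGeneric("accelMatrix"))

#' @rdname accessors
#' @export
setGeneric("timePoints", function(object) standardGeneric("timePoints"))

#' @rdname accessors
#' @export
setGeneric("intervals", function(object) standardGeneric("intervals"))

#' @rdname accessors
#' @export
setGeneric("windowStarts", function(object) standardGeneric("windowStarts"))

#' @rdname accessors
#' @export
setGeneric("windowActivities", function(object) standardGeneric("windowActivities"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("embeddingCoords", function(object) standardGeneric("embeddingCoords"))

#' @rdname accessors
#' @export
setGeneric("tsneSeed", function(object) standardGeneric("tsneSeed"))

#' @rdname accessors
#' @export
setGeneric("tsneParams", function(object) standardGeneric("tsneParams"))

#' @rdname accessors
#' @export
setGeneric("clusterIds", function(object) standardGeneric("clusterIds"))

#' @rdname accessors
#' @export
setGeneric("isOutlier", function(object) standardGeneric("isOutlier"))

#' @rdname accessors
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))

#' @rdname accessors
#' @export
setGeneric("assignmentStatus", function(object) standardGeneric("assignmentStatus"))

#' @rdname accessors
#' @export
setGeneric("clusterSummaries", function(object) standardGeneric("clusterSummaries"))

#' @rdname accessors
#' @export
setGeneric("stairClusterId", function(object) standardGeneric("stairClusterId"))

#' @rdname accessors
#' @export
setGeneric("walkClusterIds", function(object) standardGeneric("walkClusterIds"))

#' @rdname accessors
#' @export
setGeneric("finalLabels", function(object) standardGeneric("finalLabels"))

#' @rdname accessors
#' @export
setGeneric("perSeedResults", function(object) standardGeneric("perSeedResults"))

#' @rdname accessors
#' @export
setGeneric("aggregateResults", function(object) standardGeneric("aggregateResults"))

#' @rdname embedTsne
#' @export
setGeneric("embedTsne", function(x, seed, ...) standardGeneric("embedTsne"))

#' @rdname runDbscan
#' @export
setGeneric("runDbscan", function(x, eps = 3, minPts = 15L) standardGeneric("runDbscan"))
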