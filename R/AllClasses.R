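#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' GaitRecording: a tri-axial thigh accelerometer recording
#'
#' Holds one subject's raw (or filtered) tri-axial acceleration time series.
#' Acceleration is in g, time in seconds on a strictly increasing base.
#'
#' @slot subjectId single string identifying the subject.
#' @slot samplingRate sampling rate in Hz (nominally 20 for the thigh-worn
#'   monitor targeted here: 2 s windows are 40 samples wide).
#' @slot time numeric vector of sample times in seconds, strictly increasing.
#' @slot accel numeric matrix with one row per sample and exactly three
#'   columns (x, y, z), in g.
#' @slot placement `"thigh_left"` or `"thigh_right"`.
#'
#' @seealso [readRecording()], [bandpassFilter()], [segmentWindows()]
#' @export
setClass("GaitRecording",
  representation(
    subjectId = "character",
    samplingRate = "numeric",
    time = "numeric",
    accel = "matrix",
    placement = "character"
  )
)

setValidity("GaitRecording", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "'subjectId' must be a single string")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "'samplingRate' must be a single positive number")
  if (ncol(object@accel) != 3L)
    msg <- c(msg, "'accel' must have exactly 3 channels (x, y, z)")
  if (nrow(object@accel) != length(object@time))
    msg <- c(msg, "'time' and 'accel' must have the same length")
  if (length(object@time) > 1L && any(diff(object@time) <= 0))
    msg <- c(msg, "'time' must be strictly increasing")
  if (!object@placement %in% c("thigh_left", "thigh_right"))
    msg <- c(msg, "'placement' must be 'thigh_left' or 'thigh_right'")
  if (length(msg)) msg else TRUE
})

#' ActivityTrack: ground-truth activity intervals
#'
#' A sorted, non-overlapping set of annotated activity intervals
#' (seconds). Recognized activities are `flat`, `uphill`, `downhill`,
#' `upstairs`, `downstairs`; anything else is carried as `other` and
#' excluded from clustering and evaluation downstream.
#'
#' @slot intervals data.frame with columns `start`, `end` (seconds) and
#'   `activity` (character), sorted by `start`.
#'
#' @seealso [readActivityTrack()], [windowActivityLabels()]
#' @export
setClass("ActivityTrack", representation(intervals = "data.frame"))

setValidity("ActivityTrack", function(object) {
  iv <- object@intervals
  msg <- character()
  if (!all(c("start", "end", "activity") %in% names(iv)))
    return("'intervals' needs columns start, end, activity")
  if (nrow(iv)) {
    if (any(iv$start >= iv$end))
      msg <- c(msg, "each interval must satisfy start < end")
    o <- order(iv$start)
    s <- iv[o, , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)]))
      msg <- c(msg, "intervals overlap")
  }
  if (length(msg)) msg else TRUE
})

#' GaitWindows: fixed-width segmented acceleration windows
#'
#' Non-overlapping windows of filtered acceleration plus their resolved
#' per-window activity labels.
#'
#' @slot data numeric array `n x width x 3` of acceleration (g).
#' @slot windowStarts numeric vector of window start times (seconds).
#' @slot activities character vector of per-window labels after
#'   resolution mapping (see [windowActivityLabels()]).
#' @slot samplingRate sampling rate in Hz.
#' @slot windowLen window length in seconds.
#' @slot subjectId subject identifier.
#' @export
setClass("GaitWindows",
  representation(
    data = "array",
    windowStarts = "numeric",
    activities = "character",
    samplingRate = "numeric",
    windowLen = "numeric",
    subjectId = "character"
  )
)

setValidity("GaitWindows", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 3L || d[3L] != 3L)
    msg <- c(msg, "'data' must be an n x width x 3 array")
  if (d[1L] != length(object@activities) ||
      d[1L] != length(object@windowStarts))
    msg <- c(msg, "window count must match labels and start times")
  w <- round(object@windowLen * object@samplingRate)
  if (length(d) == 3L && d[2L] != w)
    msg <- c(msg, sprintf("each window must hold windowLen*samplingRate = %d samples", w))
  if (length(msg)) msg else TRUE
})

#' GaitFeatureSet: per-window feature table
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with features as rows and analysis windows as columns. The single assay
#' `"features"` holds the feature values; `colData` carries the window
#' start time and the resolved activity label of each window. Metadata
#' records the subject, the feature bank (names in evaluation order), the
#' standardization state, and any constant features zeroed during
#' standardization.
#'
#' @seealso [extractFeatures()], [standardizeFeatures()], [embedTsne()]
#' @export
setClass("GaitFeatureSet", contains = "SummarizedExperiment")

setValidity("GaitFeatureSet", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("windowStart", "activity") %in% names(cd)))
    msg <- c(msg, "colData needs 'windowStart' and 'activity'")
  if (length(msg)) msg else TRUE
})

#' TsneMap: a seeded two-dimensional t-SNE embedding
#'
#' @slot coords numeric matrix `n x 2` of embedding coordinates, one row
#'   per analysis window.
#' @slot seed integer RNG seed the embedding was produced under.
#' @slot params list of embedding parameters (perplexity, exaggeration,
#'   theta, iterations, learning rate, ...), frozen for provenance.
#' @slot windowInfo data.frame with one row per embedded window: `window`
#'   (index), `windowStart`, `activity`.
#' @seealso [embedTsne()], [sweepSeeds()], [runDbscan()]
#' @export
setClass("TsneMap",
  representation(
    coords = "matrix",
    seed = "integer",
    params = "list",
    windowInfo = "data.frame"
  )
)

setValidity("TsneMap", function(object) {
  msg <- character()
  if (ncol(object@coords) != 2L)
    msg <- c(msg, "'coords' must have 2 columns")
  if (!all(is.finite(object@coords)))
    msg <- c(msg, "'coords' must be finite")
  if (nrow(object@windowInfo) != nrow(object@coords))
    msg <- c(msg, "'windowInfo' must have one row per embedded point")
  if (length(msg)) msg else TRUE
})

#' DbscanClustering: density-based cluster labels on an embedding
#'
#' @slot clusterId integer vector, one entry per point; cluster ids are
#'   contiguous from 1 in order of cluster creation, `0` marks an outlier.
#' @slot eps neighborhood radius in embedding-distance units (closed ball,
#'   distance <= eps).
#' @slot minPts minimum neighborhood size (the point itself counts) for a
#'   core point.
#' @seealso [runDbscan()], [assignClusters()]
#' @export
setClass("DbscanClustering",
  representation(clusterId = "integer", eps = "numeric", minPts = "integer")
)

setValidity("DbscanClustering", function(object) {
  msg <- character()
  if (object@eps <= 0) msg <- c(msg, "'eps' must be positive")
  if (object@minPts < 1L) msg <- c(msg, "'minPts' must be >= 1")
  ids <- object@clusterId
  k <- max(ids, 0L)
  if (k > 0L && !all(seq_len(k) %in% ids))
    msg <- c(msg, "cluster ids must be contiguous from 1")
  if (any(ids < 0L)) msg <- c(msg, "cluster ids must be >= 0 (0 = outlier)")
  if (length(msg)) msg else TRUE
})

#' WalkGaussian: Gaussian fitted to the main walking cluster
#'
#' Single-component Gaussian (maximum-likelihood mean and covariance)
#' fitted to the points of the main walking cluster; candidate cluster
#' centroids are scored by their negative log-likelihood under it.
#'
#' @slot mean numeric 2-vector.
#' @slot cov 2 x 2 symmetric positive-definite covariance matrix
#'   (regularized by `1e-6 * I` when near-singular).
#' @seealso [fitWalkGaussian()], [centroidNll()]
#' @export
setClass("WalkGaussian", representation(mean = "numeric", cov = "matrix"))

setValidity("WalkGaussian", function(object) {
  msg <- character()
  if (length(object@mean) != 2L) msg <- c(msg, "'mean' must be a 2-vector")
  if (!all(dim(object@cov) == c(2L, 2L)))
    msg <- c(msg, "'cov' must be 2 x 2")
  else {
    if (max(abs(object@cov - t(object@cov))) > 1e-8)
      msg <- c(msg, "'cov' must be symmetric")
    ev <- eigen(object@cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) msg <- c(msg, "'cov' must be positive-definite")
  }
  if (length(msg)) msg else TRUE
})

#' StairAssignment: final walk/stair cluster assignment
#'
#' Result of the cluster-assignment decision tree: with two clusters the
#' smaller one is the stair cluster by elimination; with three or more,
#' candidates are scored by `1 - 1/(nll * phi)` and the arg-max becomes
#' the stair cluster while all other clusters are relabeled Walk.
#'
#' @slot status `"ok"`, `"single_cluster_error"` or `"no_cluster_error"`.
#' @slot nClusters integer number of DBSCAN clusters the decision saw.
#' @slot walkIds integer ids of clusters assigned Walk (the largest
#'   cluster is always among them).
#' @slot stairId integer id of the stair cluster (`NA` on error status).
#' @slot summaries data.frame of per-cluster statistics: `cluster`,
#'   `size`, `centroidX`, `centroidY`, `compactness` (median pairwise
#'   distance), `nll`, `phi`, `score`, `role`.
#' @slot finalLabels character per-point labels after relabeling:
#'   `"Walk"`, `"Stair"` or `"Outlier"`.
#' @seealso [assignClusters()], [stairPurity()]
#' @export
setClass("StairAssignment",
  representation(
    status = "character",
    nClusters = "integer",
    walkIds = "integer",
    stairId = "integer",
    summaries = "data.frame",
    finalLabels = "character"
  )
)

setValidity("StairAssignment", function(object) {
  msg <- character()
  if (!object@status %in% c("ok", "single_cluster_error", "no_cluster_error"))
    msg <- c(msg, "invalid status")
  if (object@status == "ok") {
    if (length(object@stairId) != 1L || is.na(object@stairId))
      msg <- c(msg, "status 'ok' requires exactly one stair cluster")
    if (!all(object@finalLabels %in% c("Walk", "Stair", "Outlier")))
      msg <- c(msg, "final labels must be Walk/Stair/Outlier")
  }
  if (length(msg)) msg else TRUE
})

#' StairEvalReport: per-seed evaluation of the pipeline
#'
#' @slot perSeed data.frame with one row per t-SNE seed: `seed`, `status`,
#'   `nClusters`, `purity`, `nmiInitial`, `nmiCorrected`.
#' @slot aggregate list of means and standard deviations over seeds with
#'   status `"ok"`.
#' @slot details list (per seed) of per-cluster summary tables from the
#'   assignment step, for pooling cluster properties across seeds.
#' @slot nmiVariant string recording the NMI normalization used.
#' @seealso [evaluateSubject()], [hypothesisTests()]
#' @export
setClass("StairEvalReport",
  representation(
    perSeed = "data.frame",
    aggregate = "list",
    details = "list",
    nmiVariant = "character"
  )
)
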