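#' @include AllClasses.R AllGenerics.R dbscan.R
NULL

.coordsOf <- function(x) {
  if (is(x, "TsneMap")) embeddingCoords(x) else as.matrix(x)
}

#' Identify the main walking cluster
#'
#' The largest DBSCAN cluster (most members; outliers excluded) is taken
#' to be a walking cluster: in free-living recordings ground walking
#' dominates the data (typically 90-99% of windows), so the stair
#' cluster can never be the largest one. Equal sizes are broken toward
#' the lower cluster id.
#'
#' @param cl a [DbscanClustering-class] with at least one cluster.
#' @return the integer id of the main walking cluster.
#' @export
identifyWalkingCluster <- function(cl) {
  k <- nClusters(cl)
  if (k == 0L)
    stop("no clusters found; cannot identify a walking cluster")
  sizes <- tabulate(clusterIds(cl)[clusterIds(cl) > 0L], nbins = k)
  which.max(sizes)  # first maximum = lowest id on ties
}

#' Summarize one cluster: centroid and compactness
#'
#' The centroid is the arithmetic mean of the member coordinates; the
#' compactness is the median of all pairwise Euclidean distances within
#' the cluster (the median resists outlying members). A singleton
#' cluster gets compactness 0 with a flag.
#'
#' @param x a [TsneMap-class] or coordinate matrix.
#' @param cl the matching [DbscanClustering-class].
#' @param id cluster id to summarize.
#' @return list with `cluster`, `size`, `centroid` (2-vector),
#'   `compactness`, and `singleton` flag.
#' @export
summarizeCluster <- function(x, cl, id) {
  Y <- .coordsOf(x)
  members <- which(clusterIds(cl) == id)
  if (!length(members)) stop("cluster ", id, " has no members")
  pts <- Y[members, , drop = FALSE]
  singleton <- nrow(pts) < 2L
  comp <- if (singleton) 0 else stats::median(stats::dist(pts))
  list(cluster = as.integer(id), size = nrow(pts),
       centroid = colMeans(pts), compactness = comp, singleton = singleton)
}

#' Fit a single Gaussian to the main walking cluster
#'
#' Maximum-likelihood mean and covariance of the walking-cluster points
#' (a one-component Gaussian mixture), forming the distribution against
#' which candidate cluster centroids are scored. A near-singular
#' covariance is regularized by adding `1e-6 * I`.
#'
#' @param x a [TsneMap-class] or coordinate matrix.
#' @param cl the matching [DbscanClustering-class].
#' @param walkId id of the main walking cluster (needs >= 3 members).
#' @return a [WalkGaussian-class].
#' @export
fitWalkGaussian <- function(x, cl, walkId) {
  Y <- .coordsOf(x)
  pts <- Y[clusterIds(cl) == walkId, , drop = FALSE]
  if (nrow(pts) < 3L)
    stop("walking cluster needs at least 3 members to fit a Gaussian")
  mu <- colMeans(pts)
  cc <- sweep(pts, 2L, mu)
  sigma <- crossprod(cc) / nrow(pts)   # MLE (1/n) covariance
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8)
    sigma <- sigma + diag(1e-6, 2L)
  new("WalkGaussian", mean = mu, cov = sigma)
}

#' Negative log-likelihood of a centroid under the walking Gaussian
#'
#' `-log` of the bivariate normal density at `K`; strictly increasing in
#' the Mahalanobis distance of `K` from the walking-cluster mean, so
#' centroids far from the main walking cluster score high.
#'
#' @param g a [WalkGaussian-class].
#' @param K numeric 2-vector (a candidate cluster centroid).
#' @return the negative log-likelihood (scalar).
#' @export
centroidNll <- function(g, K) {
  stopifnot(length(K) == 2L)
  md2 <- stats::mahalanobis(matrix(K, 1L), g@mean, g@cov)
  0.5 * (2 * log(2 * pi) + determinant(g@cov, logarithm = TRUE)$modulus[1L] + md2)
}

#' Compactness rank factors for candidate clusters
#'
#' Candidates (main walking cluster and outliers excluded) are ordered
#' from least compact (largest median pairwise distance) to most
#' compact; the least compact gets rank factor 1, each subsequent
#' cluster adds the reward, so the most compact cluster carries the
#' largest factor. The reward defaults to 0.05: cluster compactness
#' separated stair from extraneous walking clusters only weakly in
#' validation, so it enters as a deliberately weak multiplicative
#' weighting next to the distance term. Equal compactness values are
#' ordered by larger negative log-likelihood first toward the compact
#' end.
#'
#' @param summaries data.frame with columns `compactness` and `nll`, one
#'   row per candidate cluster.
#' @param reward rank increment (default 0.05).
#' @return numeric vector of rank factors `phi` (>= 1), aligned with the
#'   rows of `summaries`.
#' @export
rankFactors <- function(summaries, reward = 0.05) {
  m <- nrow(summaries)
  if (!m) return(numeric())
  # least compact first; ties: larger nll is ranked as more compact
  o <- order(-summaries$compactness, summaries$nll)
  phi <- numeric(m)
  phi[o] <- 1 + reward * (seq_len(m) - 1L)
  phi
}

#' Stair-cluster scores
#'
#' Computes `P = 1 - 1 / (nll * phi)` for each candidate cluster: the
#' probability of being the stair cluster grows with the centroid's
#' misfit to the walking Gaussian (`nll`) and with the compactness rank
#' factor (`phi`). The value is used as a ranking score (arg-max), not a
#' calibrated probability: candidates whose centroid sits well inside
#' the walking Gaussian can have `nll <= 0`, which is floored at `1e-9`
#' and drives the score strongly negative, effectively disqualifying
#' them.
#'
#' @param summaries data.frame with columns `nll` and `phi`.
#' @return `summaries` with a `score` column appended.
#' @export
stairScores <- function(summaries) {
  nll <- ifelse(summaries$nll <= 0, 1e-9, summaries$nll)
  summaries$score <- 1 - 1 / (nll * summaries$phi)
  summaries
}

#' Assign walk and stair identities to DBSCAN clusters
#'
#' The decision tree of the stair-recognition algorithm:
#' \itemize{
#'   \item 0 clusters: status `"no_cluster_error"`.
#'   \item 1 cluster: status `"single_cluster_error"` (a lone cluster
#'     gives no contrast to assign).
#'   \item 2 clusters: the larger is the Walking cluster, the other is
#'     the Stair cluster by elimination.
#'   \item 3 or more: the largest cluster is Walking; the remaining
#'     candidates are scored with [stairScores()] (negative
#'     log-likelihood of their centroid under the walking Gaussian times
#'     the compactness rank factor) and the arg-max becomes the Stair
#'     cluster; every other cluster is relabeled Walk.
#' }
#' Score ties are broken toward the larger negative log-likelihood. After
#' relabeling only two identities remain (plus outliers).
#'
#' @param x a [TsneMap-class] or coordinate matrix.
#' @param cl the matching [DbscanClustering-class].
#' @param reward compactness rank increment, see [rankFactors()].
#' @return a [StairAssignment-class].
#' @export
assignClusters <- function(x, cl, reward = 0.05) {
  Y <- .coordsOf(x)
  ids <- clusterIds(cl)
  k <- nClusters(cl)
  emptySummary <- data.frame(cluster = integer(), size = integer(),
                             centroidX = numeric(), centroidY = numeric(),
                             compactness = numeric(), nll = numeric(),
                             phi = numeric(), score = numeric(),
                             role = character())
  if (k == 0L)
    return(new("StairAssignment", status = "no_cluster_error",
               nClusters = 0L, walkIds = integer(), stairId = NA_integer_,
               summaries = emptySummary,
               finalLabels = rep("Outlier", length(ids))))
  walkId <- identifyWalkingCluster(cl)
  sums <- do.call(rbind, lapply(seq_len(k), function(id) {
    s <- summarizeCluster(Y, cl, id)
    data.frame(cluster = s$cluster, size = s$size,
               centroidX = s$centroid[1L], centroidY = s$centroid[2L],
               compactness = s$compactness, nll = NA_real_,
               phi = NA_real_, score = NA_real_, role = "candidate",
               stringsAsFactors = FALSE)
  }))
  sums$role[sums$cluster == walkId] <- "walk_main"
  if (k == 1L)
    return(new("StairAssignment", status = "single_cluster_error",
               nClusters = 1L, walkIds = walkId, stairId = NA_integer_,
               summaries = sums,
               finalLabels = ifelse(ids == 0L, "Outlier", "Walk")))

  cand <- which(sums$cluster != walkId)
  g <- fitWalkGaussian(Y, cl, walkId)
  sums$nll[cand] <- vapply(cand, function(i)
    centroidNll(g, c(sums$centroidX[i], sums$centroidY[i])), numeric(1L))

  if (k == 2L) {
    stairId <- sums$cluster[cand]
    sums$phi[cand] <- 1
    sums <- stairScores(sums)
  } else {
    sums$phi[cand] <- rankFactors(sums[cand, , drop = FALSE], reward)
    sums <- stairScores(sums)
    sc <- sums$score[cand]
    best <- cand[order(-sc, -sums$nll[cand])][1L]  # ties: larger nll wins
    stairId <- sums$cluster[best]
  }
  sums$role[sums$cluster == stairId] <- "stair"
  sums$role[sums$role == "candidate"] <- "walk_extra"
  lab <- ifelse(ids == 0L, "Outlier", ifelse(ids == stairId, "Stair", "Walk"))
  new("StairAssignment", status = "ok", nClusters = k,
      walkIds = as.integer(sums$cluster[sums$cluster != stairId]),
      stairId = as.integer(stairId), summaries = sums, finalLabels = lab)
}

#' Write per-window relabeled identities to CSV
#'
#' One row per embedded window with its map coordinates and final
#' identity (`Walk`, `Stair` or `Outlier`), for plotting relabeled maps.
#'
#' @param result a [StairAssignment-class].
#' @param map the [TsneMap-class] the assignment was computed on.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeRelabeled <- function(result, map, path) {
  Y <- embeddingCoords(map)
  utils::write.csv(
    data.frame(x = Y[, 1L], y = Y[, 2L],
               window_index = map@windowInfo$window,
               label = finalLabels(result)),
    path, row.names = FALSE)
  invisible(path)
}

#' Serialize a stair assignment to JSON
#'
#' Writes per-cluster summaries (size, centroid, compactness, nll, phi,
#' score, role), the final identities and the status.
#'
#' @param result a [StairAssignment-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeAssignment <- function(result, path) {
  jsonlite::write_json(
    list(status = assignmentStatus(result),
         n_clusters = result@nClusters,
         walk_clusters = walkClusterIds(result),
         stair_cluster = stairClusterId(result),
         summaries = clusterSummaries(result)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
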