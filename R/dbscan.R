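#' @include AllClasses.R AllGenerics.R
NULL

#' Density-based clustering of an embedding (DBSCAN)
#'
#' Standard DBSCAN semantics: a core point has at least `minPts`
#' neighbors within distance `eps` (closed ball, the point itself
#' counts); clusters are the maximal density-connected sets of core
#' points plus the border points they reach; everything else is an
#' outlier. Clusters are grown from seed points in index order, so
#' cluster ids are contiguous from 1 in order of creation and a border
#' point reachable from several clusters joins the earliest-created one
#' — a fully deterministic variant.
#'
#' Zero clusters is a valid output (handled by the assignment decision
#' tree downstream).
#'
#' @param x a [TsneMap-class] or a numeric `n x 2` coordinate matrix.
#' @param eps neighborhood radius in embedding-distance units (default 3,
#'   tuned for 2-D t-SNE maps of per-subject window features).
#' @param minPts minimum neighborhood size for a core point (default 15).
#' @return a [DbscanClustering-class].
#' @export
#' @rdname runDbscan
setMethod("runDbscan", "TsneMap", function(x, eps = 3, minPts = 15L) {
  runDbscan(embeddingCoords(x), eps = eps, minPts = minPts)
})

#' @export
#' @rdname runDbscan
setMethod("runDbscan", "matrix", function(x, eps = 3, minPts = 15L) {
  stopifnot(eps > 0, minPts >= 1)
  n <- nrow(x)
  minPts <- as.integer(minPts)
  if (n == 0L)
    return(new("DbscanClustering", clusterId = integer(), eps = eps,
               minPts = minPts))
  D <- as.matrix(stats::dist(x))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(nb) >= minPts
  cl <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (cl[i] != 0L || !core[i]) next
    cur <- cur + 1L
    cl[i] <- cur
    queue <- i
    head <- 1L
    while (head <= length(queue)) {
      p <- queue[head]
      head <- head + 1L
      fresh <- nb[[p]][cl[nb[[p]]] == 0L]
      if (length(fresh)) {
        cl[fresh] <- cur
        queue <- c(queue, fresh[core[fresh]])
      }
    }
  }
  new("DbscanClustering", clusterId = cl, eps = eps, minPts = minPts)
})
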