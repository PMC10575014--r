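#' @include AllClasses.R AllGenerics.R
NULL

# run fn under a fixed seed, restoring the caller's RNG state afterwards
.withSeed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Embed standardized features in two dimensions with seeded t-SNE
#'
#' Projects the window-by-feature matrix to 2-D using t-SNE with
#' Euclidean distances on the standardized features, fixed perplexity and
#' exaggeration, and a seed-controlled random initialization so repeated
#' calls with the same inputs are bit-identical. No PCA pre-reduction is
#' applied. The exaggeration factor multiplies the joint probabilities
#' during the first 250 optimization iterations (early exaggeration).
#' The gradient is computed exactly for up to 2000 points and with the
#' Barnes-Hut approximation (theta 0.5) above that; all solver settings
#' are frozen into the returned parameter list.
#'
#' @param x a standardized [GaitFeatureSet-class], or a numeric
#'   windows-by-features matrix.
#' @param seed integer RNG seed (the embedding is deterministic given the
#'   matrix, seed and parameters).
#' @param perplexity t-SNE perplexity (default 30); requires more than
#'   `3 * perplexity` windows.
#' @param exaggeration early-exaggeration multiplier (default 4).
#' @param maxIter number of gradient iterations (default 1000).
#' @param eta learning rate (default 200).
#' @param theta Barnes-Hut accuracy parameter; `NULL` (default) selects 0
#'   (exact) for up to 2000 points and 0.5 above.
#' @param ... passed to methods.
#' @return a [TsneMap-class].
#' @export
#' @rdname embedTsne
setMethod("embedTsne", "GaitFeatureSet", function(x, seed, ...) {
  if (!isTRUE(S4Vectors::metadata(x)$standardized))
    warning("feature set is not standardized; t-SNE distances will be dominated by high-variance features")
  map <- embedTsne(featureMatrix(x), seed, ...)
  map@windowInfo <- data.frame(window = seq_len(ncol(x)),
                               windowStart = windowStarts(x),
                               activity = windowActivities(x),
                               stringsAsFactors = FALSE)
  map
})

#' @export
#' @rdname embedTsne
setMethod("embedTsne", "matrix", function(x, seed, perplexity = 30,
                                          exaggeration = 4, maxIter = 1000,
                                          eta = 200, theta = NULL, ...) {
  n <- nrow(x)
  if (anyNA(x)) stop("feature matrix contains missing values")
  if (n <= 3 * perplexity)
    stop(sprintf("t-SNE needs more than 3 * perplexity = %g windows (have %d); reduce the perplexity",
                 3 * perplexity, n))
  if (is.null(theta)) theta <- if (n > 2000) 0.5 else 0
  seed <- as.integer(seed)
  res <- .withSeed(seed, function() {
    y0 <- matrix(stats::rnorm(n * 2L, sd = 1e-4), n, 2L)
    Rtsne::Rtsne(x, dims = 2, perplexity = perplexity, theta = theta,
                 max_iter = maxIter, eta = eta,
                 exaggeration_factor = exaggeration,
                 Y_init = y0, stop_lying_iter = 250L, mom_switch_iter = 250L,
                 pca = FALSE, normalize = FALSE, check_duplicates = FALSE,
                 num_threads = 1)
  })
  params <- list(perplexity = perplexity, exaggeration = exaggeration,
                 nDims = 2L, distance = "euclidean-on-standardized-features",
                 theta = theta, maxIter = maxIter, eta = eta,
                 stopLyingIter = 250L, momSwitchIter = 250L,
                 initSd = 1e-4, pca = FALSE)
  new("TsneMap", coords = res$Y, seed = seed, params = params,
      windowInfo = data.frame(window = seq_len(n), windowStart = NA_real_,
                              activity = NA_character_,
                              stringsAsFactors = FALSE))
})

#' Embed a feature set under several seeds
#'
#' Produces one embedding per seed (each independently deterministic);
#' varying the t-SNE seed and re-running the downstream clustering is how
#' per-subject results are aggregated.
#'
#' @param x a standardized [GaitFeatureSet-class] or feature matrix.
#' @param seeds integer vector of seeds (default 1:5).
#' @param ... passed on to [embedTsne()].
#' @return named list of [TsneMap-class] objects (`"seed1"`, ...).
#' @export
sweepSeeds <- function(x, seeds = 1:5, ...) {
  if (!length(seeds)) stop("'seeds' must be non-empty")
  out <- lapply(seeds, function(s) embedTsne(x, s, ...))
  names(out) <- paste0("seed", seeds)
  out
}

#' Write an embedding to CSV
#'
#' @param map a [TsneMap-class].
#' @param path output CSV path (columns x, y, window_index, label).
#' @return `path`, invisibly.
#' @export
writeEmbedding <- function(map, path) {
  utils::write.csv(
    data.frame(x = map@coords[, 1L], y = map@coords[, 2L],
               window_index = map@windowInfo$window,
               label = map@windowInfo$activity),
    path, row.names = FALSE)
  invisible(path)
}

#' Plot a 2-D embedding colored by label
#'
#' @param map a [TsneMap-class].
#' @param labels per-point labels to color by; defaults to the activity
#'   labels carried by the embedding.
#' @param file optional PNG path; when given the plot is written there.
#' @param main plot title.
#' @return invisibly, the label levels and colors used.
#' @export
plotEmbedding <- function(map, labels = windowActivities(map), file = NULL,
                          main = sprintf("t-SNE (seed %d)", tsneSeed(map))) {
  labels <- factor(labels)
  cols <- grDevices::hcl.colors(max(3L, nlevels(labels)), "Dark 3")
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(map@coords, col = cols[as.integer(labels)], pch = 19,
                 cex = 0.5, xlab = "tSNE 1", ylab = "tSNE 2", main = main)
  graphics::legend("topright", legend = levels(labels),
                   col = cols[seq_len(nlevels(labels))], pch = 19, cex = 0.8)
  invisible(list(levels = levels(labels), colors = cols))
}
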