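#' @include AllClasses.R AllGenerics.R ingest.R
NULL

# Zero-phase filtering: forward-backward pass with even-reflection padding
# and steady-state initial conditions (past inputs = first sample, past
# outputs = first sample times the DC gain). Exactly rejects DC and keeps
# edge transients out of the retained segment. Pad covers ~3 time constants
# of the slowest pole; capped at n - 1 for short inputs.
.filtfiltPad <- function(b, a, x, npad) {
  nb <- length(b)
  na_ <- length(a)
  nx <- length(x)
  npad <- min(npad, nx - 1L)
  hdc <- sum(b) / sum(a)
  onePass <- function(z) {
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z[1L], nb - 1L),
                              init.y = rep(z[1L] * hdc, na_ - 1L)))
  }
  xp <- c(x[(npad + 1L):2L], x, x[(nx - 1L):(nx - npad)])
  y <- rev(onePass(xp))
  y <- rev(onePass(y))
  y[(npad + 1L):(npad + nx)]
}

#' Band-pass filter a recording
#'
#' Applies a zero-phase 4th-order Butterworth band-pass (forward-backward
#' pass) to each acceleration channel, preserving 0.4-3 Hz by default.
#' This removes the gravitational (near-DC) component and high-frequency
#' muscle/impact artifact while leaving gait-cadence content intact, and
#' introduces no phase shift so windows stay aligned with their labels.
#'
#' @param rec a [GaitRecording-class].
#' @param low,high pass-band edges in Hz; must satisfy
#'   `0 < low < high < samplingRate / 2`.
#' @return a filtered [GaitRecording-class] of identical length.
#' @export
bandpassFilter <- function(rec, low = 0.4, high = 3) {
  fs <- samplingRate(rec)
  if (low <= 0 || low >= high)
    stop("need 0 < low < high")
  if (high >= fs / 2)
    stop(sprintf("high cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 high, fs / 2))
  # order-2 prototype -> 4th-order band-pass
  bf <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  npad <- ceiling(3 * fs / low)
  acc <- accelMatrix(rec)
  filt <- apply(acc, 2L, function(ch) .filtfiltPad(bf$b, bf$a, ch, npad))
  gaitRecording(timePoints(rec), filt, samplingRate = fs,
                subjectId = subjectId(rec), placement = rec@placement)
}

#' Segment a recording into non-overlapping analysis windows
#'
#' Cuts the recording into fixed-width windows of `windowLen` seconds
#' (40 samples at the default 20 Hz) with no overlap; a trailing partial
#' window is dropped. Per-window labels are attached from the annotation
#' track via [windowActivityLabels()].
#'
#' @param rec a (typically band-pass filtered) [GaitRecording-class].
#' @param track an [ActivityTrack-class] with ground-truth intervals.
#' @param windowLen window length in seconds (default 2).
#' @param level label resolution level, see [resolveActivity()].
#' @return a [GaitWindows-class].
#' @export
segmentWindows <- function(rec, track, windowLen = 2,
                           level = c("level0", "level1")) {
  level <- match.arg(level)
  fs <- samplingRate(rec)
  w <- round(windowLen * fs)
  acc <- accelMatrix(rec)
  n <- nrow(acc) %/% w
  if (n < 1L)
    stop(sprintf("recording too short: %d samples, need at least %d for one window",
                 nrow(acc), w))
  idx <- seq_len(n * w)
  arr <- array(0, dim = c(n, w, 3L))
  for (ax in 1:3)
    arr[, , ax] <- matrix(acc[idx, ax], nrow = n, ncol = w, byrow = TRUE)
  starts <- timePoints(rec)[seq(1L, by = w, length.out = n)]
  labels <- windowActivityLabels(track, starts, windowLen, level)
  new("GaitWindows", data = arr, windowStarts = starts, activities = labels,
      samplingRate = fs, windowLen = windowLen, subjectId = subjectId(rec))
}

## ---- feature bank -------------------------------------------------------

.timeStats <- function(v) {
  n <- length(v)
  m <- mean(v)
  vv <- stats::var(v)
  cv <- v - m
  m2 <- mean(cv^2)
  skew <- if (m2 > 0) mean(cv^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean(cv^4) / m2^2 - 3 else 0
  pos <- v >= 0
  zc <- sum(diff(pos) != 0)
  c(mean = m, var = vv, sd = sqrt(vv), rms = sqrt(mean(v^2)),
    min = min(v), max = max(v), range = max(v) - min(v),
    iqr = stats::IQR(v), skew = skew, kurt = kurt, zcr = zc,
    sma = mean(abs(v)), energy = sum(v^2) / n)
}

.freqStats <- function(v, fs) {
  n <- length(v)
  sp <- abs(stats::fft(v))^2 / n
  half <- 2:(n %/% 2 + 1L)              # positive frequencies, DC excluded
  freqs <- (half - 1L) * fs / n
  p <- sp[half]
  tot <- sum(p)
  if (tot <= 0) {
    domFreq <- 0; domPow <- 0; sentropy <- 0
  } else {
    k <- which.max(p)
    domFreq <- freqs[k]
    domPow <- p[k]
    pr <- p / tot
    pr <- pr[pr > 0]
    sentropy <- -sum(pr * log(pr)) / log(length(half))
  }
  band <- function(lo, hi, closed) {
    sel <- if (closed) freqs >= lo & freqs <= hi else freqs >= lo & freqs < hi
    sum(p[sel])
  }
  c(domfreq = domFreq, dompow = domPow, spec_entropy = sentropy,
    bp_0.4_1 = band(0.4, 1, FALSE), bp_1_2 = band(1, 2, FALSE),
    bp_2_3 = band(2, 3, TRUE))
}

.safeCor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Default per-window feature bank
#'
#' A named registry of feature extractors evaluated in declared order.
#' Each extractor receives a `width x 3` window matrix plus the sampling
#' rate and returns a named numeric vector. The default bank computes,
#' per axis, time-domain statistics (mean, variance, standard deviation,
#' RMS, min, max, range, IQR, skewness, kurtosis, zero-crossing count,
#' signal magnitude area, energy), frequency-domain features on the
#' window FFT (dominant frequency, its power, normalized spectral
#' entropy, band powers over 0.4-1, 1-2 and 2-3 Hz), the three pairwise
#' axis correlations, and the time-domain set on the resultant magnitude
#' (73 features in total). Degenerate conventions: skewness, kurtosis,
#' spectral entropy and correlations of constant signals are 0.
#'
#' An alternative bank (e.g. one matching an externally published feature
#' list) can be passed to [extractFeatures()] as a registry of the same
#' shape.
#'
#' @return named list of extractor functions `function(win, fs)`.
#' @export
defaultFeatureBank <- function() {
  axisTime <- function(ax) {
    force(ax)
    function(win, fs) {
      out <- .timeStats(win[, ax])
      names(out) <- paste(c("x", "y", "z")[ax], names(out), sep = ".")
      out
    }
  }
  axisFreq <- function(ax) {
    force(ax)
    function(win, fs) {
      out <- .freqStats(win[, ax], fs)
      names(out) <- paste(c("x", "y", "z")[ax], names(out), sep = ".")
      out
    }
  }
  list(
    time_x = axisTime(1L), time_y = axisTime(2L), time_z = axisTime(3L),
    freq_x = axisFreq(1L), freq_y = axisFreq(2L), freq_z = axisFreq(3L),
    axis_corr = function(win, fs) {
      c(corr.xy = .safeCor(win[, 1L], win[, 2L]),
        corr.xz = .safeCor(win[, 1L], win[, 3L]),
        corr.yz = .safeCor(win[, 2L], win[, 3L]))
    },
    time_mag = function(win, fs) {
      out <- .timeStats(sqrt(rowSums(win^2)))
      names(out) <- paste("mag", names(out), sep = ".")
      out
    }
  )
}

#' Extract per-window features
#'
#' Evaluates a feature bank on every window and assembles the result into
#' a [GaitFeatureSet-class] (features x windows), with window start times
#' and activity labels in `colData` and the bank recorded in the
#' metadata. Any extractor producing a non-finite value is an error
#' naming the feature and the window.
#'
#' @param ws a [GaitWindows-class].
#' @param bank feature registry, see [defaultFeatureBank()].
#' @return an unstandardized [GaitFeatureSet-class].
#' @export
extractFeatures <- function(ws, bank = defaultFeatureBank()) {
  d <- dim(ws@data)
  if (d[1L] < 1L) stop("no windows to extract features from")
  fs <- samplingRate(ws)
  one <- function(i) {
    win <- ws@data[i, , ]
    # unname the registry so feature names are the extractors' own
    unlist(unname(lapply(bank, function(f) f(win, fs))))
  }
  first <- one(1L)
  X <- vapply(seq_len(d[1L]), one, numeric(length(first)))
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("feature '%s' is not finite in window %d",
                 names(first)[bad[1L, 1L]], bad[1L, 2L]))
  rownames(X) <- names(first)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = X),
    colData = S4Vectors::DataFrame(windowStart = windowStarts(ws),
                                   activity = windowActivities(ws)),
    metadata = list(subjectId = subjectId(ws), samplingRate = fs,
                    windowLen = ws@windowLen, standardized = FALSE,
                    constantFeatures = character(),
                    featureBank = names(bank),
                    nFeatures = length(first))
  )
  new("GaitFeatureSet", se)
}

#' Standardize a feature set per subject
#'
#' Column-wise z-scoring over the subject's own windows: each feature is
#' centered to mean 0 and scaled to sample standard deviation 1 (n - 1
#' denominator). Features constant across windows are set to 0 and
#' recorded in `metadata(x)$constantFeatures` so they cannot inject
#' NaN into the embedding. Idempotent on non-constant features.
#'
#' @param x a [GaitFeatureSet-class] with at least 2 windows.
#' @return the standardized [GaitFeatureSet-class].
#' @export
standardizeFeatures <- function(x) {
  X <- SummarizedExperiment::assay(x, "features")
  if (ncol(X) < 2L) stop("need at least 2 windows to standardize")
  mu <- rowMeans(X)
  sd_ <- apply(X, 1L, stats::sd)
  const <- sd_ == 0
  Z <- (X - mu) / ifelse(const, 1, sd_)
  Z[const, ] <- 0
  SummarizedExperiment::assay(x, "features") <- Z
  md <- S4Vectors::metadata(x)
  md$standardized <- TRUE
  md$constantFeatures <- rownames(X)[const]
  S4Vectors::metadata(x) <- md
  x
}

#' Keep only windows with a scored activity label
#'
#' Drops windows labeled `"other"` (unknown activity or mostly uncovered
#' time); these are excluded from clustering and evaluation.
#'
#' @param x a [GaitFeatureSet-class].
#' @return the subset [GaitFeatureSet-class].
#' @export
keepScoredWindows <- function(x) {
  x[, windowActivities(x) != "other"]
}

#' Write a feature table to CSV with a JSON metadata sidecar
#'
#' @param x a [GaitFeatureSet-class].
#' @param path output CSV path (windows x features); a `.json` sidecar
#'   with the feature names, flags and bank is written next to it.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(x, path) {
  df <- data.frame(windowStart = windowStarts(x),
                   activity = windowActivities(x),
                   featureMatrix(x), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  md <- S4Vectors::metadata(x)
  jsonlite::write_json(md[c("subjectId", "samplingRate", "windowLen",
                            "standardized", "constantFeatures",
                            "featureBank", "nFeatures")],
                       sub("\\.csv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
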