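#' @include AllClasses.R AllGenerics.R
NULL

.ACTIVITIES <- c("flat", "uphill", "downhill", "upstairs", "downstairs")
.STAIR_ACTIVITIES <- c("upstairs", "downstairs")
# tie-break precedence in window labeling: stairs first, so that purity
# evaluation is conservative when a window straddles a stair boundary
.LABEL_PRECEDENCE <- c("upstairs", "downstairs", "Walk",
                       "flat", "uphill", "downhill")

#' Construct a GaitRecording
#'
#' @param time numeric vector of sample times (seconds), strictly increasing.
#' @param accel numeric matrix `n x 3` of acceleration in g (columns x, y, z).
#' @param samplingRate sampling rate in Hz; default 20.
#' @param subjectId subject identifier.
#' @param placement `"thigh_left"` or `"thigh_right"`.
#' @return a [GaitRecording-class] object.
#' @export
gaitRecording <- function(time, accel, samplingRate = 20,
                          subjectId = "subject", placement = "thigh_right") {
  accel <- as.matrix(accel)
  colnames(accel) <- c("x", "y", "z")
  new("GaitRecording", subjectId = subjectId, samplingRate = samplingRate,
      time = as.numeric(time), accel = accel, placement = placement)
}

#' Read a tri-axial accelerometer recording from CSV
#'
#' Expects a header row with columns `time,x,y,z`; time in seconds,
#' acceleration in g. The time base is validated to be strictly
#' increasing; gaps larger than two sample periods are collected into a
#' warning so that dropout segments can be inspected.
#'
#' @param path path to the CSV file.
#' @param samplingRate nominal sampling rate in Hz (default 20, i.e. 2 s
#'   windows are 40 samples wide).
#' @param subjectId subject identifier attached to the recording.
#' @param placement device placement, `"thigh_left"` or `"thigh_right"`.
#' @return a [GaitRecording-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(time = 0:39 / 20, x = rnorm(40), y = 0, z = 0),
#'           f, row.names = FALSE)
#' readRecording(f, subjectId = "demo")
#' @export
readRecording <- function(path, samplingRate = 20, subjectId = "subject",
                          placement = "thigh_right") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "x", "y", "z")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("recording CSV is missing column(s): ",
         paste(missing, collapse = ", "))
  for (cn in need) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(v2) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric value in column '%s' at row %d", cn, bad[1L]))
      df[[cn]] <- v2
    }
  }
  if (anyNA(df[need]))
    stop("recording CSV contains missing values at row ",
         which(!stats::complete.cases(df[need]))[1L])
  dt <- diff(df$time)
  if (any(dt <= 0))
    stop("time must be strictly increasing; violation at row ",
         which(dt <= 0)[1L] + 1L)
  gaps <- which(dt > 2 / samplingRate)
  if (length(gaps))
    warning(sprintf("%d gap(s) larger than 2 sample periods (first after t = %g s)",
                    length(gaps), df$time[gaps[1L]]))
  gaitRecording(df$time, as.matrix(df[, c("x", "y", "z")]),
                samplingRate = samplingRate, subjectId = subjectId,
                placement = placement)
}

#' Construct an ActivityTrack from a data.frame
#'
#' @param intervals data.frame with columns `start`, `end`, `activity`.
#' @return an [ActivityTrack-class], sorted by start time.
#' @export
activityTrack <- function(intervals) {
  intervals <- intervals[order(intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  intervals$activity <- as.character(intervals$activity)
  new("ActivityTrack", intervals = intervals)
}

#' Read ground-truth activity intervals from CSV
#'
#' Expects columns `start,end,label` (seconds; label strings are matched
#' case-insensitively). Labels other than flat, uphill, downhill,
#' upstairs, downstairs are mapped to `"other"` with a warning; such
#' windows are excluded from clustering and evaluation downstream.
#' Overlapping intervals are an error.
#'
#' @param path path to the CSV file.
#' @return an [ActivityTrack-class].
#' @export
readActivityTrack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start", "end", "label")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("label CSV is missing column(s): ", paste(missing, collapse = ", "))
  lab <- tolower(trimws(df$label))
  unknown <- unique(lab[!lab %in% .ACTIVITIES])
  if (length(unknown)) {
    warning("unknown activity label(s) mapped to 'other': ",
            paste(unknown, collapse = ", "))
    lab[!lab %in% .ACTIVITIES] <- "other"
  }
  iv <- data.frame(start = df$start, end = df$end, activity = lab,
                   stringsAsFactors = FALSE)
  if (any(iv$start >= iv$end))
    stop("interval with start >= end at row ", which(iv$start >= iv$end)[1L])
  o <- order(iv$start)
  s <- iv[o, , drop = FALSE]
  if (nrow(s) > 1L) {
    bad <- which(s$start[-1L] < s$end[-nrow(s)])
    if (length(bad))
      stop(sprintf("overlapping intervals: rows %d and %d (as sorted)",
                   bad[1L], bad[1L] + 1L))
  }
  activityTrack(iv)
}

#' Map activity labels to a resolution level
#'
#' At level 0 the ground-walking labels flat, uphill and downhill are
#' consolidated into a single `"Walk"` label, while upstairs and
#' downstairs are kept separate; at level 1 all five activities are kept.
#' The mapping is idempotent (`"Walk"` maps to `"Walk"`), and `"other"`
#' always stays `"other"`.
#'
#' @param labels character vector of activity labels.
#' @param level `"level0"` or `"level1"`.
#' @return character vector of mapped labels.
#' @export
resolveActivity <- function(labels, level = c("level0", "level1")) {
  level <- match.arg(level)
  if (level == "level1") return(labels)
  out <- labels
  out[out %in% c("flat", "uphill", "downhill")] <- "Walk"
  out
}

#' Label analysis windows from an interval annotation track
#'
#' Each window `[s, s + windowLen)` receives the (resolution-mapped)
#' activity covering the majority of its duration. Time not covered by
#' any interval counts as `"other"`; a window with more than 50% other or
#' uncovered time is labeled `"other"` (and excluded from clustering and
#' evaluation downstream). Ties in covered duration are broken toward the
#' rarer stair labels so purity evaluation stays conservative.
#'
#' @param track an [ActivityTrack-class].
#' @param starts numeric vector of window start times (seconds).
#' @param windowLen window length in seconds (> 0).
#' @param level label resolution level, see [resolveActivity()].
#' @return character vector of per-window labels.
#' @export
windowActivityLabels <- function(track, starts, windowLen = 2,
                                 level = c("level0", "level1")) {
  stopifnot(windowLen > 0)
  level <- match.arg(level)
  iv <- intervals(track)
  mapped <- resolveActivity(iv$activity, level)
  vapply(starts, function(s) {
    e <- s + windowLen
    ov <- pmin(iv$end, e) - pmax(iv$start, s)
    ov[ov < 0] <- 0
    dur <- tapply(ov, mapped, sum)
    dur <- dur[dur > 0]
    otherTime <- windowLen - sum(dur[names(dur) != "other"])
    if (otherTime > windowLen / 2) return("other")
    dur <- dur[names(dur) != "other"]
    if (!length(dur)) return("other")
    best <- names(dur)[dur == max(dur)]
    prec <- c(.LABEL_PRECEDENCE, setdiff(best, .LABEL_PRECEDENCE))
    prec[prec %in% best][1L]
  }, character(1L))
}

#' Read a pipeline configuration file
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON configuration and merges it over
#' the pipeline defaults. Recognized entries: `sampling_rate`,
#' `window_len`, `resolution_level`, `band_low`, `band_high`,
#' `perplexity`, `exaggeration`, `eps`, `min_points`, `reward`, `seeds`.
#'
#' @param path path to the configuration file; `NULL` returns the defaults.
#' @return named list of configuration values.
#' @export
readPipelineConfig <- function(path = NULL) {
  defaults <- list(
    sampling_rate = 20, window_len = 2, resolution_level = "level0",
    band_low = 0.4, band_high = 3, perplexity = 30, exaggeration = 4,
    eps = 3, min_points = 15L, reward = 0.05, seeds = 1:5
  )
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    warning("ignoring unknown config entries: ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, cfg[intersect(names(cfg), names(defaults))])
}
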