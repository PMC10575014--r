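#' @include AllClasses.R AllGenerics.R ingest.R embedding.R
NULL

#' Simulate a 2-D embedding with walk/stair cluster geometry
#'
#' Draws points from isotropic Gaussians: one dominant walking cluster,
#' one stair cluster, and optional extraneous walking clusters. The
#' defaults emulate the geometry observed in per-subject t-SNE maps of
#' free-living walking data: walking dominates (stair fraction 1-10% of
#' points), the stair cluster is the most distant from the walking
#' cluster, and it is more compact than the walking clusters. Specs that
#' violate those constraints (stair closer than an extraneous cluster,
#' or stair spread not below the walk spread) are rejected.
#'
#' Stair points are labeled `upstairs`/`downstairs` (alternating halves)
#' and all other points `Walk`, so purity and NMI can be computed on the
#' simulated truth.
#'
#' @param nTotal total number of points (default 1000).
#' @param stairFraction fraction of stair points, in `[0.01, 0.10]`
#'   (default 0.05).
#' @param walkCenter,stairCenter cluster centers (2-vectors).
#' @param walkSpread,stairSpread isotropic standard deviations; the
#'   stair cluster must be tighter than the walking cluster.
#' @param extraCenters list of 2-vectors, centers of extraneous walking
#'   clusters (all closer to the walk center than the stair cluster).
#' @param extraSpreads,extraSizes numeric vectors aligned with
#'   `extraCenters`.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return list with `coords` (matrix), `cluster` (generating component:
#'   `"walk"`, `"stair"`, `"extra1"`, ...), and `activity` (ground-truth
#'   label per point).
#' @export
simEmbedding <- function(nTotal = 1000, stairFraction = 0.05,
                         walkCenter = c(0, 0), walkSpread = 6,
                         stairCenter = c(30, 0), stairSpread = 1.5,
                         extraCenters = list(c(-16, 6), c(8, -15)),
                         extraSpreads = c(2.5, 2.5),
                         extraSizes = c(45, 45),
                         seed = 1) {
  if (stairFraction < 0.01 || stairFraction > 0.10)
    stop("'stairFraction' must be in [0.01, 0.10]")
  if (stairSpread >= walkSpread)
    stop("stair cluster must be tighter than the walking cluster (stairSpread < walkSpread)")
  dWalk <- function(p) sqrt(sum((p - walkCenter)^2))
  if (length(extraCenters)) {
    if (any(vapply(extraCenters, dWalk, numeric(1)) >= dWalk(stairCenter)))
      stop("stair cluster must be the most distant cluster from the walking cluster")
    stopifnot(length(extraSpreads) == length(extraCenters),
              length(extraSizes) == length(extraCenters))
  }
  nStair <- round(nTotal * stairFraction)
  nWalk <- nTotal - nStair - sum(extraSizes)
  if (nWalk < sum(extraSizes) + nStair)
    stop("walking cluster must dominate the data")
  .withSeed(seed, function() {
    blob <- function(n, center, spread)
      cbind(stats::rnorm(n, center[1L], spread),
            stats::rnorm(n, center[2L], spread))
    coords <- blob(nWalk, walkCenter, walkSpread)
    cluster <- rep("walk", nWalk)
    for (j in seq_along(extraCenters)) {
      coords <- rbind(coords, blob(extraSizes[j], extraCenters[[j]],
                                   extraSpreads[j]))
      cluster <- c(cluster, rep(paste0("extra", j), extraSizes[j]))
    }
    coords <- rbind(coords, blob(nStair, stairCenter, stairSpread))
    cluster <- c(cluster, rep("stair", nStair))
    activity <- ifelse(cluster == "stair", "upstairs", "Walk")
    stairIdx <- which(cluster == "stair")
    if (length(stairIdx) > 1L)
      activity[stairIdx[seq(ceiling(length(stairIdx) / 2) + 1L,
                            length(stairIdx))]] <- "downstairs"
    list(coords = coords, cluster = cluster, activity = activity)
  })
}

.DEFAULT_GAIT <- list(
  # fundamental cadence (Hz) per activity: hill cadences sit within a
  # small offset of flat walking (same gait, slightly altered tempo);
  # stair cadences are markedly slower (the walker must slow down to
  # traverse stairs)
  cadence = c(flat = 1.8, uphill = 1.72, downhill = 1.88,
              upstairs = 0.95, downstairs = 1.05),
  # base acceleration amplitude (g) of the fundamental per activity
  amplitude = c(flat = 0.40, uphill = 0.37, downhill = 0.44,
                upstairs = 0.22, downstairs = 0.26),
  # per-axis multipliers of the base amplitude (x: thigh longitudinal);
  # ground activities share one mix — hill walking is the same gait
  axisMix = rbind(x = c(flat = 1.0, uphill = 1.0, downhill = 1.0,
                        upstairs = 1.0, downstairs = 1.0),
                  y = c(flat = 0.45, uphill = 0.45, downhill = 0.45,
                        upstairs = 0.62, downstairs = 0.62),
                  z = c(flat = 0.70, uphill = 0.70, downhill = 0.70,
                        upstairs = 0.52, downstairs = 0.52)),
  # phase-structure sharing: ground activities reuse one gait pattern
  # and the two stair directions another (both are the same slow
  # step-over-step gait, so stair ambulation forms a single cluster)
  phaseGroup = c(flat = "ground", uphill = "ground", downhill = "ground",
                 upstairs = "stair", downstairs = "stair"),
  # relative strength of the 2nd and 3rd harmonic
  harmonics = c(0.5, 0.25),
  # gravity projection (g) onto the axes for an upright thigh
  gravity = c(x = 0.95, y = 0.10, z = 0.25),
  noiseSd = 0.06,
  # stride-to-stride variability: stationary s.d. of the slow AR(1)
  # wander of instantaneous cadence (relative) and amplitude (relative)
  cadenceWanderSd = 0.03,
  amplitudeWanderSd = 0.12,
  # bout-to-bout tempo variation (relative s.d. of the bout mean
  # cadence): walkers pick a different pace per ground bout, while
  # stair cadence is constrained by the stair geometry
  boutTempoSd = c(ground = 0.04, stair = 0.01)
)

# slow AR(1) wander with unit stationary s.d.
.arWander <- function(n, rho = 0.98) {
  innov <- stats::rnorm(n, 0, sqrt(1 - rho^2))
  as.numeric(stats::filter(innov, rho, method = "recursive",
                           init = stats::rnorm(1L)))
}

#' Default free-living walking schedule
#'
#' A repeating 840 s block — flat 300 s, uphill 150 s, flat 98 s,
#' upstairs 22 s, flat 100 s, downhill 150 s, downstairs 20 s — repeated
#' `blocks` times. Ten blocks give a 140 min recording with 95% ground
#' walking and 5% stair ambulation, the class imbalance typical of
#' free-living data. Bout boundaries are aligned to the 2 s analysis
#' grid so every window's ground truth is exact.
#'
#' @param blocks number of 840 s blocks (default 10).
#' @return data.frame with columns `activity` and `duration` (seconds).
#' @export
defaultSchedule <- function(blocks = 10) {
  unit <- data.frame(
    activity = c("flat", "uphill", "flat", "upstairs", "flat",
                 "downhill", "downstairs"),
    duration = c(300, 150, 98, 22, 100, 150, 20),
    stringsAsFactors = FALSE)
  out <- unit[rep(seq_len(nrow(unit)), blocks), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a labeled tri-axial gait recording
#'
#' Generates a synthetic free-living recording as a schedule of activity
#' bouts. Each bout is, per axis, a fundamental sinusoid at the
#' activity's cadence plus two harmonics, an activity-specific amplitude
#' mix across axes, a constant gravity projection, and Gaussian noise.
#' The inter-axis and inter-harmonic phase structure is drawn once per
#' activity for the whole recording — a subject's gait pattern is
#' repeatable across bouts, which is the premise of per-subject
#' modeling — while every bout starts at a random point of the gait
#' cycle and jitters its cadence slightly. The label track matches the
#' schedule exactly (no sampling in the schedule). Stair bouts have slower
#' cadence and lower amplitude than ground walking; hill cadences sit
#' close to flat walking — the signal differences the pipeline's
#' frequency and energy features are designed to pick up. This harmonic
#' model drives the feature bank realistically but is not a
#' biomechanical gait simulation.
#'
#' @param schedule data.frame with columns `activity`, `duration`
#'   (seconds); default [defaultSchedule()] (140 min, 5% stairs).
#' @param samplingRate sampling rate in Hz (default 20).
#' @param gait list of gait-model parameters; see the package defaults
#'   in the source. Partial lists are merged over the defaults.
#' @param subjectId subject id for the generated recording.
#' @param seed integer seed; generation is a pure function of
#'   (arguments, seed).
#' @return list with `recording` ([GaitRecording-class]) and `track`
#'   ([ActivityTrack-class]).
#' @export
simRecording <- function(schedule = defaultSchedule(), samplingRate = 20,
                         gait = list(), subjectId = "sim", seed = 1) {
  stopifnot(nrow(schedule) > 0)
  g <- utils::modifyList(.DEFAULT_GAIT, gait)
  stopifnot(all(schedule$activity %in% names(g$cadence)))
  .withSeed(seed, function() {
    dt <- 1 / samplingRate
    segs <- vector("list", nrow(schedule))
    starts <- cumsum(c(0, schedule$duration))
    # per-gait phase structure, fixed for the whole recording (ground
    # activities share one pattern; see .DEFAULT_GAIT$phaseGroup)
    groups <- unique(g$phaseGroup[unique(schedule$activity)])
    groupPhase <- lapply(stats::setNames(groups, groups), function(gr)
      matrix(stats::runif(9L, 0, 2 * pi), 3L, 3L))  # axis x harmonic
    phase <- lapply(g$phaseGroup, function(gr) groupPhase[[gr]])
    for (b in seq_len(nrow(schedule))) {
      act <- schedule$activity[b]
      nb <- round(schedule$duration[b] * samplingRate)
      grp <- if (g$phaseGroup[[act]] == "ground") "ground" else "stair"
      f0 <- g$cadence[[act]] * (1 + stats::rnorm(1L, 0, g$boutTempoSd[[grp]]))
      # instantaneous cadence and amplitude wander slowly (stride-to-
      # stride variability), so bouts of the same activity are
      # statistically identical rather than carrying a bout signature
      finst <- f0 * (1 + g$cadenceWanderSd * .arWander(nb))
      cyc <- cumsum(finst) * dt + stats::runif(1L)  # bout starts mid-cycle
      am <- 1 + g$amplitudeWanderSd * .arWander(nb)
      amp <- g$amplitude[[act]]
      seg <- matrix(0, nb, 3L)
      for (ax in 1:3) {
        ph <- phase[[act]][ax, ]
        base <- sin(2 * pi * cyc + ph[1L]) +
          g$harmonics[1L] * sin(2 * pi * 2 * cyc + ph[2L]) +
          g$harmonics[2L] * sin(2 * pi * 3 * cyc + ph[3L])
        seg[, ax] <- g$gravity[[ax]] + amp * g$axisMix[ax, act] * am * base +
          stats::rnorm(nb, 0, g$noiseSd)
      }
      segs[[b]] <- seg
    }
    acc <- do.call(rbind, segs)
    time <- (seq_len(nrow(acc)) - 1L) * dt
    track <- activityTrack(data.frame(
      start = starts[-length(starts)], end = starts[-1L],
      activity = schedule$activity, stringsAsFactors = FALSE))
    list(recording = gaitRecording(time, acc, samplingRate = samplingRate,
                                   subjectId = subjectId),
         track = track)
  })
}

#' Simulate a cohort of subjects with idiosyncratic gait
#'
#' Generates one labeled recording per subject, jittering the cadence
#' and amplitude tables multiplicatively per subject so that pooled
#' multi-subject embeddings cluster by individual rather than by
#' activity — the phenomenon that motivates per-subject modeling.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param schedule per-subject bout schedule (default [defaultSchedule()]).
#' @param cadenceJitter,amplitudeJitter standard deviations of the
#'   per-subject log-normal multipliers (defaults 0.12 and 0.20).
#' @param samplingRate sampling rate in Hz.
#' @param seed integer seed.
#' @return list of per-subject lists with `recording`, `track`,
#'   `subjectId`.
#' @export
simCohort <- function(nSubjects, schedule = defaultSchedule(),
                      cadenceJitter = 0.12, amplitudeJitter = 0.20,
                      samplingRate = 20, seed = 1) {
  stopifnot(nSubjects >= 1)
  mult <- .withSeed(seed, function() {
    lapply(seq_len(nSubjects), function(i)
      list(cad = exp(stats::rnorm(1L, 0, cadenceJitter)),
           amp = exp(stats::rnorm(1L, 0, amplitudeJitter)),
           seed = sample.int(1e6, 1L)))
  })
  lapply(seq_len(nSubjects), function(i) {
    id <- sprintf("S%02d", i)
    gait <- list(cadence = .DEFAULT_GAIT$cadence * mult[[i]]$cad,
                 amplitude = .DEFAULT_GAIT$amplitude * mult[[i]]$amp)
    sim <- simRecording(schedule, samplingRate = samplingRate, gait = gait,
                        subjectId = id, seed = mult[[i]]$seed)
    c(sim, list(subjectId = id))
  })
}
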