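#' @include AllClasses.R AllGenerics.R stair-cluster.R embedding.R features.R
NULL

#' Stair cluster purity
#'
#' Fraction of windows in the detected stair cluster whose ground-truth
#' activity is `upstairs` or `downstairs`. By construction this is the
#' precision of the stair cluster against the ground truth. Undefined
#' (returned as `NA`) when the assignment carries an error status.
#'
#' @param result a [StairAssignment-class].
#' @param truth character vector of per-window ground-truth activity
#'   labels, aligned with the assignment's points.
#' @return purity in `[0, 1]`, or `NA` if no stair cluster was assigned.
#' @export
stairPurity <- function(result, truth) {
  if (assignmentStatus(result) != "ok") return(NA_real_)
  members <- finalLabels(result) == "Stair"
  if (!any(members)) return(NA_real_)
  if (length(truth) != length(finalLabels(result)))
    stop("truth labels do not match the number of assigned points")
  mean(truth[members] %in% .STAIR_ACTIVITIES)
}

#' Normalized mutual information between two labelings
#'
#' Mutual information of the two label vectors normalized by the
#' arithmetic mean of their entropies, in `[0, 1]`; symmetric in its
#' arguments and invariant to label permutation. Defined as 0 when
#' either labeling is constant (no information to share).
#'
#' @param pred,truth label vectors (character or factor) of equal length.
#' @return NMI in `[0, 1]`.
#' @export
nmiScore <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("label vectors must have equal length")
  if (!length(pred)) stop("empty label vectors")
  tab <- table(pred, truth)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx == 0 || hy == 0) return(0)
  nz <- pxy > 0
  mi <- sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
  mi <- max(mi, 0)  # guard tiny negative rounding
  min(mi / ((hx + hy) / 2), 1)
}

#' Evaluate the full pipeline for one subject across t-SNE seeds
#'
#' For every seed: embed the standardized features, cluster the
#' embedding with DBSCAN, run the walk/stair assignment, and score the
#' result with stair purity, the initial NMI (raw DBSCAN cluster ids
#' against the binary walk/stair ground truth, before any correction)
#' and the corrected NMI (the two-identity relabeled model against the
#' same truth). Outlier windows are excluded from both NMI and purity,
#' and windows labeled `"other"` are dropped before embedding. Seeds
#' ending in an error status are recorded but excluded from the
#' aggregate mean and standard deviation.
#'
#' @param x a standardized [GaitFeatureSet-class].
#' @param seeds integer t-SNE seeds (default 1:5).
#' @param eps,minPts DBSCAN parameters (defaults 3 and 15).
#' @param reward compactness rank increment (default 0.05).
#' @param ... further arguments to [embedTsne()] (perplexity,
#'   exaggeration, ...).
#' @return a [StairEvalReport-class].
#' @export
evaluateSubject <- function(x, seeds = 1:5, eps = 3, minPts = 15L,
                            reward = 0.05, ...) {
  x <- keepScoredWindows(x)
  truthAll <- ifelse(windowActivities(x) %in% .STAIR_ACTIVITIES,
                     "Stair", "Walk")
  rows <- list()
  details <- list()
  for (s in seeds) {
    map <- embedTsne(x, s, ...)
    cl <- runDbscan(map, eps = eps, minPts = minPts)
    res <- assignClusters(map, cl, reward = reward)
    keep <- !isOutlier(cl)
    if (assignmentStatus(res) == "ok" && any(keep)) {
      purity <- stairPurity(res, windowActivities(x))
      nmi0 <- nmiScore(as.character(clusterIds(cl)[keep]), truthAll[keep])
      nmi1 <- nmiScore(finalLabels(res)[keep], truthAll[keep])
    } else {
      purity <- NA_real_; nmi0 <- NA_real_; nmi1 <- NA_real_
    }
    rows[[length(rows) + 1L]] <- data.frame(
      seed = s, status = assignmentStatus(res), nClusters = res@nClusters,
      purity = purity, nmiInitial = nmi0, nmiCorrected = nmi1,
      stringsAsFactors = FALSE)
    details[[paste0("seed", s)]] <- clusterSummaries(res)
  }
  perSeed <- do.call(rbind, rows)
  ok <- perSeed$status == "ok"
  agg <- list(
    nOk = sum(ok),
    meanPurity = if (any(ok)) mean(perSeed$purity[ok]) else NA_real_,
    sdPurity = if (sum(ok) > 1L) stats::sd(perSeed$purity[ok]) else NA_real_,
    meanNmiInitial = if (any(ok)) mean(perSeed$nmiInitial[ok]) else NA_real_,
    sdNmiInitial = if (sum(ok) > 1L) stats::sd(perSeed$nmiInitial[ok]) else NA_real_,
    meanNmiCorrected = if (any(ok)) mean(perSeed$nmiCorrected[ok]) else NA_real_,
    sdNmiCorrected = if (sum(ok) > 1L) stats::sd(perSeed$nmiCorrected[ok]) else NA_real_
  )
  new("StairEvalReport", perSeed = perSeed, aggregate = agg,
      details = details, nmiVariant = "arithmetic-mean-entropy")
}

#' Pool stair and extraneous-walk cluster properties from a report
#'
#' Collects, across seeds, the compactness and negative log-likelihood
#' of the detected stair clusters and of the extraneous walking clusters
#' (clusters other than the main walking cluster that were relabeled
#' Walk), as input to [hypothesisTests()].
#'
#' @param reports one [StairEvalReport-class] or a list of them
#'   (e.g. several subjects).
#' @return list with data.frames `stair` and `extraneous`, each with
#'   columns `compactness` and `nll`.
#' @export
poolClusterProperties <- function(reports) {
  if (is(reports, "StairEvalReport")) reports <- list(reports)
  pick <- function(role) {
    do.call(rbind, lapply(reports, function(r)
      do.call(rbind, lapply(r@details, function(d)
        d[d$role == role, c("compactness", "nll")]))))
  }
  stair <- pick("stair")
  extraneous <- pick("walk_extra")
  list(stair = if (is.null(stair)) data.frame(compactness = numeric(), nll = numeric()) else stair,
       extraneous = if (is.null(extraneous)) data.frame(compactness = numeric(), nll = numeric()) else extraneous)
}

#' Hypothesis statistics on cluster properties and NMI improvement
#'
#' Statistical checks of the assumptions behind the stair score and of
#' the correction step:
#' \itemize{
#'   \item Shapiro-Wilk normality per group (stair / extraneous walk)
#'     and property (negative log-likelihood, compactness);
#'   \item Wilcoxon rank-sum between groups for both properties (the
#'     distribution-free comparison used when normality fails);
#'   \item two-sample t-test on compactness;
#'   \item right-tailed paired t-test of corrected vs initial NMI across
#'     subjects (is the correction a systematic improvement?).
#' }
#' Entries whose group sizes do not support a test are `NA`.
#'
#' @param stair,extraneous data.frames with columns `compactness` and
#'   `nll` (e.g. from [poolClusterProperties()]).
#' @param nmiInitial,nmiCorrected optional paired per-subject NMI
#'   vectors.
#' @param alpha significance level recorded in the report (default 0.05).
#' @return list with elements `shapiro` (data.frame), `wilcoxon`
#'   (data.frame), `tCompactness`, `tNmiPaired` (each a list with
#'   statistic and p-value), and `alpha`.
#' @export
hypothesisTests <- function(stair, extraneous, nmiInitial = NULL,
                            nmiCorrected = NULL, alpha = 0.05) {
  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  shapiroRow <- function(group, property, v) {
    p <- if (length(v) >= 3L && stats::sd(v) > 0)
      safe(stats::shapiro.test(v)$p.value) else NULL
    data.frame(group = group, property = property,
               n = length(v), p = if (is.null(p)) NA_real_ else p)
  }
  shapiro <- rbind(
    shapiroRow("stair", "nll", stair$nll),
    shapiroRow("stair", "compactness", stair$compactness),
    shapiroRow("extraneous", "nll", extraneous$nll),
    shapiroRow("extraneous", "compactness", extraneous$compactness))
  wilcoxRow <- function(property, a, b) {
    ok <- length(a) >= 3L && length(b) >= 3L
    w <- if (ok) safe(stats::wilcox.test(a, b, exact = FALSE)) else NULL
    data.frame(property = property,
               statistic = if (is.null(w)) NA_real_ else unname(w$statistic),
               p = if (is.null(w)) NA_real_ else w$p.value)
  }
  wilcoxon <- rbind(
    wilcoxRow("nll", stair$nll, extraneous$nll),
    wilcoxRow("compactness", stair$compactness, extraneous$compactness))
  tc <- if (nrow(stair) >= 3L && nrow(extraneous) >= 3L)
    safe(stats::t.test(stair$compactness, extraneous$compactness)) else NULL
  tn <- NULL
  if (!is.null(nmiInitial) && !is.null(nmiCorrected) &&
      length(nmiInitial) >= 3L &&
      length(nmiInitial) == length(nmiCorrected)) {
    d <- nmiCorrected - nmiInitial
    if (stats::sd(d) > 0) {
      tn <- safe(stats::t.test(nmiCorrected, nmiInitial, paired = TRUE,
                               alternative = "greater"))
    } else {
      # degenerate: all differences identical; no variance to test against
      tn <- list(statistic = NA_real_,
                 p.value = if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5)
    }
  }
  list(
    shapiro = shapiro,
    wilcoxon = wilcoxon,
    tCompactness = list(
      statistic = if (is.null(tc)) NA_real_ else unname(tc$statistic),
      p = if (is.null(tc)) NA_real_ else tc$p.value),
    tNmiPaired = list(
      statistic = if (is.null(tn)) NA_real_ else unname(tn$statistic),
      p = if (is.null(tn)) NA_real_ else tn$p.value),
    alpha = alpha
  )
}

#' Write an evaluation report to JSON (and optionally CSV)
#'
#' @param report a [StairEvalReport-class].
#' @param path output JSON path; when `csv` is `TRUE` a per-seed CSV is
#'   written next to it.
#' @param csv also write the per-seed table as CSV.
#' @return `path`, invisibly.
#' @export
writeEvalReport <- function(report, path, csv = FALSE) {
  jsonlite::write_json(
    list(perSeed = perSeedResults(report),
         aggregate = aggregateResults(report),
         nmiVariant = report@nmiVariant),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  if (csv)
    utils::write.csv(perSeedResults(report),
                     sub("\\.json$", ".csv", path), row.names = FALSE)
  invisible(path)
}
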