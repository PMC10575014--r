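mkAssignment <- function(finalLabels, status = "ok") {
  new("StairAssignment", status = status, nClusters = 2L, walkIds = 1L,
      stairId = if (status == "ok") 2L else NA_integer_,
      summaries = data.frame(), finalLabels = finalLabels)
}

test_that("stair purity counts stair-truth windows inside the stair cluster", {
  res <- mkAssignment(c("Stair", "Stair", "Stair", "Stair", "Walk", "Walk"))
  truth <- c("upstairs", "downstairs", "Walk", "upstairs", "Walk", "Walk")
  expect_equal(stairPurity(res, truth), 0.75)
  expect_equal(stairPurity(res, c(rep("upstairs", 4), "Walk", "Walk")), 1.0)
  expect_equal(stairPurity(res, rep("Walk", 6)), 0.0)
  # undefined on error status: NA, not 0
  bad <- mkAssignment(rep("Walk", 6), status = "single_cluster_error")
  expect_true(is.na(stairPurity(bad, truth)))
  expect_error(stairPurity(res, truth[1:3]), "match")
})

test_that("NMI endpoints: identical labelings give 1, independence gives 0", {
  a <- rep(c("Walk", "Stair"), c(60, 40))
  expect_equal(nmiScore(a, a), 1.0)
  # permuting label names changes nothing
  b <- ifelse(a == "Walk", "x", "y")
  expect_equal(nmiScore(b, a), 1.0)
  # uniform 2x2 contingency table = independent labelings
  p <- rep(c("A", "B"), 2)
  q <- rep(c("C", "C", "D", "D"))
  expect_equal(nmiScore(p, q), 0.0)
  # constant labeling carries no information
  expect_equal(nmiScore(rep("A", 10), rep(c("x", "y"), 5)), 0)
  expect_error(nmiScore(a[1:5], a), "equal length")
})

test_that("NMI is symmetric and matches the entropy oracle", {
  set.seed(31)
  for (rep in 1:10) {
    a <- sample(letters[1:sample(2:5, 1)], 80, replace = TRUE)
    b <- sample(LETTERS[1:sample(2:4, 1)], 80, replace = TRUE)
    expect_equal(nmiScore(a, b), nmiOracle(a, b), tolerance = 1e-12)
    expect_equal(nmiScore(a, b), nmiScore(b, a), tolerance = 1e-12)
  }
  # the specific table [[45, 5], [5, 45]]
  a <- rep(c("w", "w", "s", "s"), c(45, 5, 5, 45))
  b <- rep(c("W", "S", "W", "S"), c(45, 5, 5, 45))
  expect_equal(nmiScore(a, b), nmiOracle(a, b), tolerance = 1e-12)
  expect_gt(nmiScore(a, b), 0.5)
})

test_that("evaluateSubject reports per-seed metrics on a clusterable subject", {
  sim <- simRecording(defaultSchedule(blocks = 3), seed = 21)
  fs <- buildFeatureSet(sim$recording, sim$track)
  rep <- evaluateSubject(fs, seeds = 1:2, maxIter = 500)
  ps <- perSeedResults(rep)
  expect_equal(nrow(ps), 2L)
  agg <- aggregateResults(rep)
  okRows <- ps[ps$status == "ok", ]
  if (nrow(okRows)) {
    expect_true(all(okRows$purity >= 0 & okRows$purity <= 1))
    expect_true(all(okRows$nmiInitial >= 0 & okRows$nmiInitial <= 1))
    expect_equal(agg$meanPurity, mean(okRows$purity))
  }
  f <- tempfile(fileext = ".json")
  writeEvalReport(rep, f, csv = TRUE)
  expect_true(file.exists(f))
  expect_true(file.exists(sub("\\.json$", ".csv", f)))
})

test_that("a constant-activity subject never yields a stair finding", {
  # a lone dense cluster triggers the single-cluster error; when the
  # homogeneous map happens to fragment, any assigned "stair" cluster
  # contains no stair-truth windows, so purity stays 0
  sched <- data.frame(activity = "flat", duration = 600)
  sim <- simRecording(sched, seed = 5)
  fs <- buildFeatureSet(sim$recording, sim$track)
  rep <- evaluateSubject(fs, seeds = 1:2, maxIter = 400)
  ps <- perSeedResults(rep)
  expect_true(all(is.na(ps$purity) | ps$purity == 0))
  expect_true(all(is.na(ps$purity[ps$status != "ok"])))
  # the error rule itself, where it is forced: one cluster -> error
  Y <- matrix(rnorm(400, sd = 0.5), 200, 2)
  r1 <- assignClusters(Y, runDbscan(Y, eps = 3, minPts = 15L))
  expect_equal(assignmentStatus(r1), "single_cluster_error")
})

test_that("hypothesis statistics behave under null and shifted groups", {
  set.seed(63)
  null1 <- data.frame(compactness = rnorm(50, 5), nll = rnorm(50, 20))
  null2 <- data.frame(compactness = rnorm(50, 5), nll = rnorm(50, 20))
  ht <- hypothesisTests(null1, null2)
  expect_gt(ht$wilcoxon$p[ht$wilcoxon$property == "nll"], 0.05)
  expect_equal(nrow(ht$shapiro), 4L)

  shifted <- data.frame(compactness = rnorm(50, 5 - 3), nll = rnorm(50, 23))
  ht2 <- hypothesisTests(shifted, null2)
  expect_lt(ht2$wilcoxon$p[ht2$wilcoxon$property == "nll"], 0.05)
  expect_lt(ht2$tCompactness$p, 0.05)

  # paired NMI with no difference carries no improvement signal
  nmi <- runif(8, 0.2, 0.6)
  ht3 <- hypothesisTests(null1, null2, nmiInitial = nmi, nmiCorrected = nmi)
  expect_gte(ht3$tNmiPaired$p, 0.5)
  # a systematic improvement is detected
  ht4 <- hypothesisTests(null1, null2, nmiInitial = nmi,
                         nmiCorrected = nmi + runif(8, 0.02, 0.1))
  expect_lt(ht4$tNmiPaired$p, 0.05)
})

test_that("cluster properties pool by role across seeds", {
  sums <- data.frame(cluster = 1:3, size = c(100, 20, 15),
                     centroidX = 0, centroidY = 0,
                     compactness = c(5, 2, 1), nll = c(NA, 8, 30),
                     phi = c(NA, 1, 1.05), score = c(NA, .875, .968),
                     role = c("walk_main", "walk_extra", "stair"))
  rep <- new("StairEvalReport",
             perSeed = data.frame(seed = 1, status = "ok", nClusters = 3,
                                  purity = 1, nmiInitial = .5,
                                  nmiCorrected = .6),
             aggregate = list(), details = list(seed1 = sums, seed2 = sums),
             nmiVariant = "arithmetic-mean-entropy")
  pooled <- poolClusterProperties(rep)
  expect_equal(nrow(pooled$stair), 2L)
  expect_equal(nrow(pooled$extraneous), 2L)
  expect_equal(pooled$stair$nll, c(30, 30))
})
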