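mkClusters <- function(ids, eps = 3, minPts = 15L) {
  new("DbscanClustering", clusterId = as.integer(ids), eps = eps,
      minPts = minPts)
}

test_that("the largest cluster is the walking cluster, lower id on ties", {
  expect_equal(identifyWalkingCluster(mkClusters(rep(c(1, 2), c(900, 50)))), 1L)
  expect_equal(identifyWalkingCluster(
    mkClusters(rep(c(1, 2, 3), c(50, 900, 30)))), 2L)
  expect_equal(identifyWalkingCluster(mkClusters(rep(c(1, 2), c(100, 100)))), 1L)
  expect_error(identifyWalkingCluster(mkClusters(rep(0, 10))), "no clusters")
})

test_that("cluster summaries: mean centroid and median pairwise compactness", {
  Y <- rbind(c(0, 0), c(0, 1), c(0, 2))
  s <- summarizeCluster(Y, mkClusters(c(1, 1, 1)), 1)
  expect_equal(s$centroid, c(0, 1))
  expect_equal(s$compactness, 1)  # pairwise distances {1, 1, 2}

  Y2 <- rbind(c(0, 0), c(3, 4))
  s2 <- summarizeCluster(Y2, mkClusters(c(1, 1)), 1)
  expect_equal(s2$centroid, c(1.5, 2))
  expect_equal(s2$compactness, 5)

  # compactness is invariant to rigid motion
  set.seed(8)
  P <- matrix(rnorm(40), 20, 2)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Q <- P %*% R + rep(c(5, -3), each = 20)
  cl <- mkClusters(rep(1, 20))
  expect_equal(summarizeCluster(P, cl, 1)$compactness,
               summarizeCluster(Q, cl, 1)$compactness)

  sing <- summarizeCluster(rbind(c(1, 1)), mkClusters(1), 1)
  expect_equal(sing$compactness, 0)
  expect_true(sing$singleton)
})

test_that("walking Gaussian is the MLE fit, regularized and equivariant", {
  set.seed(123)
  Y <- matrix(rnorm(20000), 10000, 2)
  g <- fitWalkGaussian(Y, mkClusters(rep(1, 10000)), 1)
  expect_lt(max(abs(g@mean)), 0.05)
  expect_lt(max(abs(g@cov - diag(2))), 0.05)

  # collinear points: regularization keeps the covariance PD
  Yc <- cbind(1:3, (1:3) * 2)
  gc <- fitWalkGaussian(Yc, mkClusters(rep(1, 3)), 1)
  ev <- eigen(gc@cov, only.values = TRUE)$values
  expect_gt(min(ev), 0)

  # translation equivariance
  shift <- c(10, -4)
  g2 <- fitWalkGaussian(sweep(Y, 2, -shift), mkClusters(rep(1, 10000)), 1)
  expect_equal(g2@mean, g@mean + shift)
  expect_equal(g2@cov, g@cov)

  expect_error(fitWalkGaussian(Y[1:2, ], mkClusters(rep(1, 2)), 1),
               "at least 3")
})

test_that("centroid negative log-likelihood has its closed form", {
  g <- new("WalkGaussian", mean = c(0, 0), cov = diag(2))
  expect_equal(centroidNll(g, c(0, 0)), log(2 * pi), tolerance = 1e-12)
  expect_equal(centroidNll(g, c(3, 4)), log(2 * pi) + 12.5, tolerance = 1e-12)
  # the mean minimizes the nll over any candidate set
  set.seed(4)
  cands <- matrix(rnorm(40, sd = 3), 20, 2)
  nlls <- apply(cands, 1, function(K) centroidNll(g, K))
  expect_true(all(nlls >= centroidNll(g, c(0, 0))))
  # agreement with an independent density implementation
  skip_if_not_installed("mvtnorm")
  K <- c(1.3, -0.7)
  S <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  g2 <- new("WalkGaussian", mean = c(0.5, 0.2), cov = S)
  expect_equal(centroidNll(g2, K),
               -mvtnorm::dmvnorm(K, c(0.5, 0.2), S, log = TRUE),
               tolerance = 1e-12)
})

test_that("rank factors step by the reward from least to most compact", {
  s <- data.frame(compactness = c(5, 2, 1), nll = c(10, 10, 10))
  expect_equal(rankFactors(s), c(1.00, 1.05, 1.10))
  expect_equal(rankFactors(s[1, , drop = FALSE]), 1.00)
  # ties in compactness: larger nll is ranked toward the compact end
  s2 <- data.frame(compactness = c(2, 2), nll = c(50, 10))
  expect_equal(rankFactors(s2), c(1.05, 1.00))
  # custom reward
  expect_equal(rankFactors(s, reward = 0.1), c(1.0, 1.1, 1.2))
})

test_that("stair scores follow 1 - 1/(nll * phi) and are monotone", {
  s <- data.frame(nll = c(20, 5), phi = c(1.05, 1.00))
  sc <- stairScores(s)$score
  expect_equal(sc[1], 1 - 1 / 21, tolerance = 1e-12)
  expect_equal(sc[2], 0.8, tolerance = 1e-12)
  expect_gt(sc[1], sc[2])  # the nll-20 candidate wins
  # monotone in nll at fixed phi, and in phi at fixed nll
  nlls <- seq(0.5, 30, length.out = 50)
  sc2 <- stairScores(data.frame(nll = nlls, phi = 1.05))$score
  expect_true(all(diff(sc2) > 0))
  phis <- seq(1, 2, length.out = 30)
  sc3 <- stairScores(data.frame(nll = 5, phi = phis))$score
  expect_true(all(diff(sc3) > 0))
  # non-positive nll is floored, driving the score far negative
  scNeg <- stairScores(data.frame(nll = -2, phi = 1.0))$score
  expect_lt(scNeg, -1e6)
})

# geometry helpers for decision-tree tests
gauss <- function(n, cx, cy, sd, seed) {
  set.seed(seed)
  cbind(rnorm(n, cx, sd), rnorm(n, cy, sd))
}

test_that("assignment decision tree covers every branch", {
  # 0 clusters
  Y0 <- cbind(seq(0, 90, 10), 0)
  r0 <- assignClusters(Y0, runDbscan(Y0, eps = 3, minPts = 15L))
  expect_equal(assignmentStatus(r0), "no_cluster_error")

  # 1 cluster
  Y1 <- gauss(100, 0, 0, 0.5, 1)
  r1 <- assignClusters(Y1, runDbscan(Y1, eps = 3, minPts = 15L))
  expect_equal(assignmentStatus(r1), "single_cluster_error")

  # 2 clusters: the larger is Walk, the smaller is Stair by elimination
  Y2 <- rbind(gauss(900, 0, 0, 2, 2), gauss(50, 25, 0, 0.8, 3))
  cl2 <- runDbscan(Y2, eps = 3, minPts = 15L)
  r2 <- assignClusters(Y2, cl2)
  expect_equal(assignmentStatus(r2), "ok")
  stairMembers <- which(finalLabels(r2) == "Stair")
  expect_true(all(stairMembers > 900))

  # >= 3 clusters: scored via nll x phi; verify against a hand computation
  Y3 <- rbind(gauss(900, 0, 0, 2, 4),    # walk
              gauss(60, 12, 0, 1.2, 5),  # extraneous, closer
              gauss(40, 0, 30, 0.6, 6))  # stair: farther and tighter
  cl3 <- runDbscan(Y3, eps = 3, minPts = 15L)
  expect_equal(nClusters(cl3), 3L)
  r3 <- assignClusters(Y3, cl3)
  expect_equal(assignmentStatus(r3), "ok")
  sums <- clusterSummaries(r3)
  walkId <- identifyWalkingCluster(cl3)
  g <- fitWalkGaussian(Y3, cl3, walkId)
  cand <- sums[sums$cluster != walkId, ]
  nllHand <- vapply(seq_len(nrow(cand)), function(i)
    centroidNll(g, c(cand$centroidX[i], cand$centroidY[i])), numeric(1))
  phiHand <- rankFactors(data.frame(compactness = cand$compactness,
                                    nll = nllHand))
  scoreHand <- 1 - 1 / (nllHand * phiHand)
  expect_equal(cand$score, scoreHand, tolerance = 1e-12)
  expect_equal(stairClusterId(r3), cand$cluster[which.max(scoreHand)])
  # the stair cluster here is the distant tight one
  expect_true(all(which(finalLabels(r3) == "Stair") > 960))
  # the extraneous cluster was relabeled Walk
  expect_true(all(finalLabels(r3)[901:960] %in% c("Walk", "Outlier")))
  # after relabeling only two identities (plus outliers) remain
  expect_true(all(finalLabels(r3) %in% c("Walk", "Stair", "Outlier")))
})

test_that("the largest cluster is never assigned Stair", {
  set.seed(77)
  for (rep in 1:25) {
    nWalk <- sample(300:800, 1)
    nExtra <- sample(1:3, 1)
    Y <- gauss(nWalk, 0, 0, runif(1, 1.5, 3), seed = rep)
    for (j in seq_len(nExtra)) {
      ang <- runif(1, 0, 2 * pi)
      d <- runif(1, 12, 20)
      Y <- rbind(Y, gauss(sample(20:60, 1), d * cos(ang), d * sin(ang),
                          runif(1, 0.5, 1.5), seed = 100 * rep + j))
    }
    cl <- runDbscan(Y, eps = 3, minPts = 15L)
    if (nClusters(cl) < 2L) next
    r <- assignClusters(Y, cl)
    if (assignmentStatus(r) != "ok") next
    sizes <- tabulate(clusterIds(cl)[clusterIds(cl) > 0])
    expect_false(stairClusterId(r) == which.max(sizes))
  }
})

test_that("the stair choice is invariant to uniform scaling of the map", {
  Y <- rbind(gauss(600, 0, 0, 2, 10), gauss(50, 14, 3, 1.1, 11),
             gauss(35, -5, 28, 0.7, 12))
  cl <- runDbscan(Y, eps = 3, minPts = 15L)
  r <- assignClusters(Y, cl)
  for (k in c(0.5, 2, 7)) {
    clK <- runDbscan(Y * k, eps = 3 * k, minPts = 15L)
    expect_identical(clusterIds(clK), clusterIds(cl))
    rK <- assignClusters(Y * k, clK)
    expect_equal(stairClusterId(rK), stairClusterId(r))
  }
})

test_that("assignments serialize to JSON and relabeled windows to CSV", {
  Y <- rbind(gauss(200, 0, 0, 1.5, 20), gauss(30, 20, 0, 0.8, 21))
  r <- assignClusters(Y, runDbscan(Y, eps = 3, minPts = 15L))
  f <- tempfile(fileext = ".json")
  writeAssignment(r, f)
  parsed <- jsonlite::fromJSON(f)
  expect_equal(parsed$status, "ok")
  expect_equal(nrow(parsed$summaries), 2L)

  map <- new("TsneMap", coords = Y, seed = 1L,
             params = list(perplexity = 30, exaggeration = 4),
             windowInfo = data.frame(window = seq_len(nrow(Y)),
                                     windowStart = NA_real_,
                                     activity = NA_character_))
  fcsv <- tempfile(fileext = ".csv")
  writeRelabeled(r, map, fcsv)
  df <- read.csv(fcsv)
  expect_equal(df$label, finalLabels(r))
  expect_true(all(df$label %in% c("Walk", "Stair", "Outlier")))
})
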