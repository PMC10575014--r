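# Gain of the band-pass is measured by the amplitude of the FFT bin at
# the probe frequency over the central portion of the output, i.e. the
# filter's steady-state response.
fftAmplitude <- function(y, f, fs) {
  n <- length(y)
  k <- round(f * n / fs)
  2 * Mod(fft(y))[k + 1L] / n
}

probeRecording <- function(x, fs = 20) {
  gaitRecording(time = (seq_along(x) - 1L) / fs,
                accel = cbind(x, 0, 0), samplingRate = fs)
}

test_that("band-pass keeps gait frequencies and rejects DC and artifact", {
  fs <- 20
  t <- (0:599) / fs
  # 1 Hz is inside the 0.4-3 Hz band: amplitude preserved
  r1 <- bandpassFilter(probeRecording(sin(2 * pi * 1 * t)))
  a1 <- fftAmplitude(accelMatrix(r1)[100:499, 1], 1, fs)
  expect_gt(a1, 0.9)
  expect_lt(a1, 1.1)
  # constant 1 g (gravity proxy) is removed
  rDC <- bandpassFilter(probeRecording(rep(1, 600)))
  expect_lt(max(abs(accelMatrix(rDC)[, 1])), 0.01)
  # 8 Hz artifact is strongly attenuated
  r8 <- bandpassFilter(probeRecording(sin(2 * pi * 8 * t)))
  expect_lt(fftAmplitude(accelMatrix(r8)[100:499, 1], 8, fs), 0.1)
})

test_that("band-pass validates its corner frequencies", {
  rec <- probeRecording(rnorm(100))
  expect_error(bandpassFilter(rec, low = 0.4, high = 10), "Nyquist")
  expect_error(bandpassFilter(rec, low = 3, high = 0.4), "low < high")
})

test_that("filtering is linear", {
  set.seed(5)
  x <- rnorm(400)
  r1 <- bandpassFilter(probeRecording(x))
  r2 <- bandpassFilter(probeRecording(3.7 * x))
  expect_equal(accelMatrix(r2)[, 1], 3.7 * accelMatrix(r1)[, 1],
               tolerance = 1e-10)
})

emptyTrack <- function() {
  activityTrack(data.frame(start = 0, end = 1e6, activity = "flat"))
}

test_that("segmentation yields floor(duration / windowLen) whole windows", {
  fs <- 20
  rec <- probeRecording(rnorm(200), fs)
  ws <- segmentWindows(rec, emptyTrack())
  expect_equal(dim(ws@data), c(5L, 40L, 3L))

  ws1 <- segmentWindows(probeRecording(rnorm(50), fs), emptyTrack())
  expect_equal(dim(ws1@data)[1L], 1L)  # 10 trailing samples dropped

  expect_error(segmentWindows(probeRecording(rnorm(39), fs), emptyTrack()),
               "too short")
})

test_that("concatenating windows reconstructs the leading samples exactly", {
  set.seed(1)
  x <- rnorm(130)
  rec <- probeRecording(x)
  ws <- segmentWindows(rec, emptyTrack())
  rebuilt <- as.numeric(t(ws@data[, , 1]))
  expect_identical(rebuilt, x[1:120])
})

zeroWindowSet <- function(n = 2, w = 40, fs = 20) {
  new("GaitWindows", data = array(0, c(n, w, 3)),
      windowStarts = seq(0, by = 2, length.out = n),
      activities = rep("Walk", n), samplingRate = fs, windowLen = 2,
      subjectId = "t")
}

test_that("feature conventions on degenerate and sinusoidal windows", {
  fs <- zeroWindowSet()
  ft <- extractFeatures(fs)
  X <- featureMatrix(ft)
  # all-zero window: means, variances, energies and correlations all 0
  expect_true(all(X == 0))

  # unit 1 Hz sinusoid on x only: dominant frequency bin is exactly 1 Hz
  ws <- zeroWindowSet()
  tt <- (0:39) / 20
  for (i in 1:2) ws@data[i, , 1] <- sin(2 * pi * tt)
  ft2 <- extractFeatures(ws)
  X2 <- featureMatrix(ft2)
  expect_equal(unname(X2[1, "x.domfreq"]), 1.0)
  expect_equal(unname(X2[1, "y.domfreq"]), 0.0)
  # identical windows -> identical feature rows
  expect_identical(X2[1, ], X2[2, ])
  # 1 Hz sits in the [1, 2) band (bands are lower-closed)
  expect_gt(X2[1, "x.bp_1_2"], X2[1, "x.bp_2_3"])
  expect_gt(X2[1, "x.bp_1_2"], X2[1, "x.bp_0.4_1"])
})

test_that("feature extraction reports the offending feature on NaN", {
  ws <- zeroWindowSet()
  bank <- c(defaultFeatureBank(),
            list(broken = function(win, fs) c(bad = NaN)))
  expect_error(extractFeatures(ws, bank), "bad")
})

test_that("standardization gives zero-mean unit-sd columns and is idempotent", {
  set.seed(7)
  ws <- zeroWindowSet(n = 30)
  for (i in 1:30) ws@data[i, , ] <- rnorm(120)
  ft <- extractFeatures(ws)
  st <- standardizeFeatures(ft)
  X <- featureMatrix(st)
  nonconst <- setdiff(colnames(X),
                      S4Vectors::metadata(st)$constantFeatures)
  expect_lt(max(abs(colMeans(X[, nonconst]))), 1e-9)
  expect_lt(max(abs(apply(X[, nonconst], 2, sd) - 1)), 1e-9)
  # constant features are zeroed and flagged
  constCols <- S4Vectors::metadata(st)$constantFeatures
  if (length(constCols)) expect_true(all(X[, constCols] == 0))
  # applying twice changes nothing (within tolerance)
  st2 <- standardizeFeatures(st)
  expect_equal(featureMatrix(st2), X, tolerance = 1e-9)
  # closed form: a 3-point column 1,2,3 standardizes to -1, 0, 1
  expect_equal(as.numeric(scale(c(1, 2, 3))), c(-1, 0, 1))
  expect_error(standardizeFeatures(ft[, 1]), "at least 2")
})

test_that("buildFeatureSet drops 'other' windows only via keepScoredWindows", {
  sim <- simRecording(defaultSchedule(blocks = 1), seed = 2)
  fs <- buildFeatureSet(sim$recording, sim$track)
  expect_s4_class(fs, "GaitFeatureSet")
  expect_true(isTRUE(S4Vectors::metadata(fs)$standardized))
  expect_equal(ncol(fs), 420L)  # 840 s / 2 s
  expect_true(all(windowActivities(keepScoredWindows(fs)) != "other"))
})
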