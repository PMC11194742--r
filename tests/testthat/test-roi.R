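test_that("SVD aggregation returns identical-vertex input exactly", {
  x <- sin(seq(0, pi, length.out = 40)) + 0.2
  v <- matrix(rep(x, each = 5), 5, byrow = FALSE)
  expect_equal(svdFlipAggregate(v), x, tolerance = 1e-12)
  # independent of the number of identical copies
  v2 <- matrix(rep(x, each = 11), 11)
  expect_equal(svdFlipAggregate(v2), svdFlipAggregate(v),
               tolerance = 1e-12)
  # single vertex: +/- x with sign following the flip vector
  expect_equal(svdFlipAggregate(matrix(x, 1), flip = 1), x,
               tolerance = 1e-12)
  expect_equal(svdFlipAggregate(matrix(x, 1), flip = -1), -x,
               tolerance = 1e-12)
  expect_equal(svdFlipAggregate(matrix(0, 3, 10)), numeric(10))
})

test_that("SVD aggregation matches a dense eigendecomposition oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(6 * 40), 6, 40)
    flip <- sample(c(-1, 1), 6, replace = TRUE)
    got <- svdFlipAggregate(X, flip)
    # oracle via the eigendecomposition of X'X and of XX'
    eg <- eigen(crossprod(X), symmetric = TRUE)
    v1 <- eg$vectors[, 1]
    scale <- sqrt(sum(eg$values[eg$values > 0])) / sqrt(6)
    u1 <- X %*% v1 / sqrt(eg$values[1])
    sgn <- sign(sum(u1 * flip))
    expected <- sgn * scale * v1
    expect_rel_equal(got, expected, 1e-10)
  }
})

test_that("SVD aggregation is permutation-invariant and sign-equivariant", {
  set.seed(8)
  X <- matrix(rnorm(7 * 30), 7, 30)
  flip <- c(1, -1, 1, 1, -1, 1, -1)
  base <- svdFlipAggregate(X, flip)
  p <- c(3, 1, 7, 5, 2, 6, 4)
  expect_rel_equal(svdFlipAggregate(X[p, ], flip[p]), base, 1e-10)
  # flipping data and orientation together leaves the output unchanged
  expect_rel_equal(svdFlipAggregate(-X, -flip), base, 1e-10)
})

test_that("first-peak detection follows the ordering rule", {
  times <- seq(-0.1, 1, by = 0.005)
  bump <- function(c, w = 0.02) exp(-(times - c)^2 / (2 * w^2))
  expect_equal(findFirstPeak(bump(0.175), times), 0.175)
  # first prominent peak wins even when a later one is larger
  two <- bump(0.15) + 2 * bump(0.3)
  expect_equal(findFirstPeak(two, times), 0.15)
  # sub-floor ripples are skipped
  rippled <- bump(0.3) + 0.02 * bump(0.1, 0.005)
  expect_equal(findFirstPeak(rippled, times), 0.3)
  expect_error(findFirstPeak(rep(0, length(times)), times),
               "no qualifying peak")
})

test_that("noisy peak detection agrees with an exhaustive scan oracle", {
  times <- seq(-0.1, 1, by = 0.005)
  for (seed in 1:5) {
    set.seed(seed)
    x <- exp(-(times - 0.2)^2 / (2 * 0.03^2)) + rnorm(length(times),
                                                      0, 0.03)
    got <- findFirstPeak(x, times)
    # oracle: scan every interior sample in the window for the first
    # local max whose prominence (computed by brute force) passes
    win <- which(times >= 0.05 & times <= 0.5)
    floorP <- 0.1 * diff(range(x[win]))
    oracle <- NA_real_
    for (p in win) {
      if (p == 1 || p == length(x)) next
      if (!(x[p] > x[p - 1] && x[p] >= x[p + 1])) next
      lh <- which(x[seq_len(p - 1)] > x[p])
      lmin <- min(x[(if (length(lh)) max(lh) + 1 else 1):(p - 1)])
      rh <- which(x[(p + 1):length(x)] > x[p])
      rmin <- min(x[(p + 1):(if (length(rh)) p + min(rh) - 1
                             else length(x))])
      if (x[p] - max(lmin, rmin) >= floorP) { oracle <- times[p]; break }
    }
    expect_equal(got, oracle)
  }
})

test_that("windows are +/- 50 ms around the peak", {
  w <- defineWindow(0.175)
  expect_equal(c(windowStart(w), windowEnd(w)), c(0.125, 0.225))
  w2 <- defineWindow(0.185)
  expect_equal(c(windowStart(w2), windowEnd(w2)), c(0.135, 0.235))
  w3 <- defineWindow(0.05, epochSpan = c(-0.1, 1))
  expect_equal(c(windowStart(w3), windowEnd(w3)), c(0, 0.1))
  expect_error(defineWindow(0.02, epochSpan = c(0, 1)), "exceeds")
})

test_that("window means use the closed interval", {
  times <- seq(-0.1, 1, by = 0.005)
  w <- defineWindow(0.175)
  expect_equal(windowMean(rep(3.5, length(times)), times, w), 3.5)
  # linear ramp over a symmetric window -> value at the center
  ramp <- 2 * times
  expect_equal(windowMean(ramp, times, w), 2 * 0.175)
  set.seed(4)
  x <- rnorm(length(times))
  keep <- times >= 0.125 - 1e-9 & times <= 0.225 + 1e-9
  expect_equal(windowMean(x, times, w), mean(x[keep]))
  expect_equal(sum(keep), 21)  # both endpoints included at 200 Hz
  wOut <- new("TimeWindow", peakLatency = 2, start = 1.9, end = 2.1)
  expect_error(windowMean(x, times, wOut), "no time samples")
})

test_that("extracted noise-free courses reproduce amplitude x kernel", {
  cfg <- noiselessConfig(nSubjectsPerGroup = 1, nTrialsPerCondition = 2,
                         nChannels = 3, sfreq = 200,
                         amplitudeMatrix = amplitudeDesign(2, 1))
  sim <- simulateEpochs(cfg)
  tcs <- extractTimecourses(sim$epochs)
  times <- courseTimes(tcs)
  kern <- exp(-(times - 0.175)^2 / (2 * 0.04^2))
  meta <- courseMeta(tcs)
  for (i in seq_len(nrow(meta))) {
    amp <- cfg@amplitudeMatrix[meta$group[i], meta$condition[i],
                               meta$session[i]]
    expect_rel_equal(courseMatrix(tcs)[i, ], amp * kern, 1e-10)
  }
  # peak recovery on the grand average
  expect_equal(findFirstPeak(grandAverage(tcs), times), 0.175)
})
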