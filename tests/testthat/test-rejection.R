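test_that("peak-to-peak amplitudes match a brute-force recomputation", {
  e <- tinyEpochs()
  ptp <- peakToPeak(e)
  expect_equal(ptp[1, ], c(3, 0))      # bump; constant channel -> 0
  expect_equal(ptp[2, 2], 5)           # single-sample spike of height 5
  expect_true(all(ptp >= 0))
  set.seed(9)
  d <- array(rnorm(5 * 4 * 20), dim = c(5, 4, 20))
  r <- EpochsSet(d, rep("Words", 5), rep(c("grad", "mag"), 2),
                 (0:19) / 100)
  oracle <- apply(d, c(1, 2), function(v) max(v) - min(v))
  expect_equal(peakToPeak(r), oracle)
})

test_that("rejection rule keeps/rejects trials per channel-type threshold", {
  e <- tinyEpochs()
  expect_identical(applyRejection(e, c(grad = Inf, mag = Inf)),
                   rep(TRUE, 3))
  # threshold 0: every trial with any nonconstant channel goes
  expect_identical(applyRejection(e, c(grad = 0, mag = 0)),
                   rep(FALSE, 3))
  # mag-only rejection: trial 2 has the mag spike (5), trial 3 mag ptp 4
  expect_identical(applyRejection(e, c(grad = Inf, mag = 4.5)),
                   c(TRUE, FALSE, TRUE))
  expect_error(applyRejection(e, c(grad = 1)), "mag")
})

test_that("rejection with a separating threshold recovers planted artifacts", {
  sim <- artifactStudy(nPerGroup = 1, seed = 11)
  thr <- c(grad = 30, mag = 600)  # between clean max and artifact level
  masks <- lapply(sim$epochs, applyRejection, thresholds = thr)
  truth <- sim$truth$artifactTrials
  expect_setequal(rejectedKeys(sim$epochs, masks),
                  paste(truth$subject, truth$session, truth$row))
})

test_that("retention is componentwise monotone in the thresholds", {
  sim <- artifactStudy(nPerGroup = 1, seed = 5)
  grid <- c(5, 20, 80, Inf)
  for (e in sim$epochs[1:2]) {
    prev <- NULL
    for (g in grid) {
      keep <- applyRejection(e, c(grad = g, mag = 20 * g))
      if (!is.null(prev)) expect_true(all(keep >= prev))
      prev <- keep
    }
  }
})

test_that("reliability objective hits the closed-form anchors", {
  set.seed(2)
  pre <- matrix(rnorm(4 * 30), 4)
  expect_equal(reliabilityObjective(pre, pre), 1.0)
  expect_equal(reliabilityObjective(pre, -pre), -1.0)
  # zero-variance subject excluded with a warning
  pre2 <- pre
  pre2[2, ] <- 7
  expect_warning(r <- reliabilityObjective(pre2, pre), "zero-variance")
  expect_equal(r, 1.0)
})

test_that("reliability objective degrades as independent noise grows", {
  base <- sin(seq(0, 2 * pi, length.out = 60))
  obj <- sapply(c(0.1, 0.5, 2), function(s) {
    mean(sapply(1:10, function(i) {
      set.seed(1000 + i)
      pre <- t(replicate(6, base + rnorm(60, 0, s)))
      post <- t(replicate(6, base + rnorm(60, 0, s)))
      reliabilityObjective(pre, post)
    }))
  })
  expect_true(all(diff(obj) < 0))
})

test_that("grid search equals an exhaustive naive recomputation", {
  sim <- artifactStudy(nPerGroup = 2, nChannels = 4, seed = 21)
  w <- bothTypeWeights(sim$epochs[[1]])
  grid <- list(grad = c(5, 25, Inf), mag = c(100, 500, Inf))
  gs <- tuneThresholds(sim$epochs, grid, roiWeights = w)
  ref <- naiveGridSearch(sim$epochs, grid, w)
  expect_equal(searchObjective(gs), ref$objective, tolerance = 1e-12)
  expect_identical(tenableMask(gs), ref$tenable)
  best <- max(ref$objective[ref$tenable], na.rm = TRUE)
  pick <- chosenThresholds(gs)
  expect_equal(searchObjective(gs)[match(pick[1], grid$grad),
                                   match(pick[2], grid$mag)], best)
})

test_that("artifact-free noise-free data score 1 everywhere tenable", {
  cfg <- noiselessConfig(nSubjectsPerGroup = 2, nTrialsPerCondition = 3,
                         nChannels = 2, sfreq = 100)
  sim <- simulateEpochs(cfg)
  grid <- list(grad = c(0.5, 2, Inf), mag = c(10, 40, Inf))
  gs <- tuneThresholds(sim$epochs, grid)
  obj <- searchObjective(gs)
  expect_true(all(abs(obj[tenableMask(gs)] - 1) < 1e-12))
  # most permissive tenable cell chosen
  expect_identical(unname(chosenThresholds(gs)), c(Inf, Inf))
})

test_that("a zero threshold makes its whole grid row untenable", {
  sim <- artifactStudy(nPerGroup = 1, nChannels = 2, seed = 2)
  grid <- list(grad = c(0, Inf), mag = c(500, Inf))
  gs <- tuneThresholds(sim$epochs, grid)
  expect_false(any(tenableMask(gs)[1, ]))
  expect_true(all(is.na(searchObjective(gs)[1, ])))
  expect_error(
    tuneThresholds(sim$epochs, list(grad = 0, mag = 0)),
    "untenable")
})

test_that("objective is invariant to trial and channel order", {
  sim <- artifactStudy(nPerGroup = 1, nChannels = 3, seed = 13)
  grid <- list(grad = c(30, Inf), mag = c(600, Inf))
  w <- bothTypeWeights(sim$epochs[[1]])
  gs <- tuneThresholds(sim$epochs, grid, roiWeights = w)
  cp <- rev(seq_len(nChannels(sim$epochs[[1]])))
  perm <- lapply(sim$epochs, function(e) {
    tp <- rev(seq_len(nTrials(e)))
    EpochsSet(epochData(e)[tp, cp, , drop = FALSE],
              conditionLabels(e)[tp], channelTypes(e)[cp],
              epochTimes(e), subjectId = subjectId(e),
              session = sessionLabel(e), group = groupLabel(e))
  })
  gs2 <- tuneThresholds(perm, grid, roiWeights = w[cp])
  expect_equal(searchObjective(gs2), searchObjective(gs),
               tolerance = 1e-12)
})
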