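test_that("noise-free generation inverts exactly to the amplitude design", {
  cfg <- noiselessConfig(nSubjectsPerGroup = 1, nTrialsPerCondition = 3,
                         nChannels = 2, sfreq = 200,
                         amplitudeMatrix = amplitudeDesign(1.5, 0.7))
  sim <- simulateEpochs(cfg)
  expect_length(sim$epochs, 4L)  # 2 subjects x 2 sessions
  pk <- which.min(abs(epochTimes(sim$epochs[[1]]) - 0.175))
  for (e in sim$epochs) {
    expect_equal(length(unique(conditionLabels(e))), 3L)
    for (cond in unique(conditionLabels(e))) {
      tri <- which(conditionLabels(e) == cond)
      # every trial of a cell equals its mean evoked exactly
      for (j in tri[-1L])
        expect_identical(epochData(e)[j, , ], epochData(e)[tri[1L], , ])
      amp <- cfg@amplitudeMatrix[groupLabel(e), cond, sessionLabel(e)]
      # unit-scale channel at the peak sample reproduces the amplitude
      expect_equal(epochData(e)[tri[1L], 1L, pk], amp, tolerance = 1e-12)
      # second-type channel scaled by 20
      expect_equal(epochData(e)[tri[1L], 3L, pk], 20 * amp,
                   tolerance = 1e-12)
    }
  }
  expect_equal(nrow(sim$truth$artifactTrials), 0L)
})

test_that("generation is a pure function of the seed", {
  cfg <- simulationConfig(nSubjectsPerGroup = 2, nTrialsPerCondition = 4,
                          nChannels = 2, sfreq = 100, artifactRate = 0.2,
                          rngSeed = 42)
  a <- simulateEpochs(cfg)
  b <- simulateEpochs(cfg)
  expect_identical(lapply(a$epochs, epochData),
                   lapply(b$epochs, epochData))
  expect_identical(a$truth, b$truth)
  cfg@rngSeed <- 43
  c <- simulateEpochs(cfg)
  expect_false(identical(epochData(a$epochs[[1]]),
                         epochData(c$epochs[[1]])))
})

test_that("artifact counts follow the configured binomial rate", {
  # pooled artifact count over replicates vs the exact binomial 99%
  # interval at rate 0.1
  nRep <- 200
  total <- 0L
  nTrialsPerRep <- 2L * 2L * 3L * 30L
  for (i in seq_len(nRep)) {
    cfg <- simulationConfig(nSubjectsPerGroup = 1,
                            nTrialsPerCondition = 30, nChannels = 1,
                            sfreq = 40, artifactRate = 0.1,
                            rngSeed = 500 + i)
    total <- total + nrow(simulateEpochs(cfg)$truth$artifactTrials)
  }
  nTot <- nRep * nTrialsPerRep
  lim <- qbinom(c(0.005, 0.995), nTot, 0.1)
  expect_gte(total, lim[1L])
  expect_lte(total, lim[2L])
})

test_that("artifact trials dominate every clean trial's peak-to-peak", {
  sim <- artifactStudy(nPerGroup = 1, seed = 3)
  truth <- sim$truth$artifactTrials
  expect_gt(nrow(truth), 0L)
  for (e in sim$epochs) {
    ptp <- peakToPeak(e)
    tru <- truth[truth$subject == subjectId(e) &
                   truth$session == sessionLabel(e), ]
    if (!nrow(tru)) next
    for (ty in unique(tru$type)) {
      cols <- channelTypes(e) == ty
      art <- tru$row[tru$type == ty]
      cleanMax <- max(ptp[-tru$row, cols])
      # per-trial rejection statistic: max over the hit type's channels
      artMin <- min(apply(ptp[art, cols, drop = FALSE], 1L, max))
      expect_gt(artMin, cleanMax)
    }
  }
})

test_that("vertex time courses reduce to signed copies of the base", {
  x <- sin(seq(0, 2 * pi, length.out = 50))
  v <- simulateVertexTimecourses(4, x, orientationSigns = 1,
                                 noiseSd = 0)
  expect_equal(v$data, matrix(rep(x, each = 4), 4), ignore_attr = TRUE)
  signs <- c(1, -1, 1, -1)
  v2 <- simulateVertexTimecourses(4, x, orientationSigns = signs,
                                  noiseSd = 0)
  expect_equal(v2$data[2, ], -x)
  expect_identical(v2$flip, signs)
  expect_error(simulateVertexTimecourses(3, x, orientationSigns = 2),
               "orientationSigns")
})

test_that("sign-corrected vertex mean converges to the base course", {
  x <- sin(seq(0, 2 * pi, length.out = 50))
  rmse <- sapply(c(4, 64), function(nv) {
    err <- sapply(1:20, function(i) {
      v <- simulateVertexTimecourses(nv, x,
                                     orientationSigns = rep(c(1, -1),
                                                            nv / 2),
                                     noiseSd = 1, seed = 100 + i)
      est <- colMeans(v$data * v$flip)
      sqrt(mean((est - x)^2))
    })
    mean(err)
  })
  # RMSE ~ 1/sqrt(n): 16x more vertices -> ~4x smaller error
  expect_lt(rmse[2], rmse[1] / 2.5)
})

test_that("behavioral generator places the gain on Letter-post only", {
  tab <- simulateBehavioral(5, baselineMean = 10, baselineSd = 2,
                            groupTimeEffect = 5, withinSubjectSd = 0,
                            seed = 1)
  gm <- tapply(tab$score, list(tab$group, tab$time), mean)
  expect_equal(gm["Letter", "post"] - gm["Letter", "pre"], 5)
  expect_equal(gm["Language", "post"] - gm["Language", "pre"], 0)
  expect_named(tab, c("subject", "group", "time", "score"))
})
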