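# Small in-code fixtures shared across test files.

# A tiny hand-built EpochsSet: 3 trials x 2 channels x 5 samples.
tinyEpochs <- function() {
  d <- array(0, dim = c(3, 2, 5))
  d[1, 1, ] <- c(0, 1, 3, 1, 0)    # ptp 3
  d[1, 2, ] <- 2                   # constant, ptp 0
  d[2, 1, ] <- c(-1, 0, 0, 0, 1)   # ptp 2
  d[2, 2, ] <- c(0, 0, 5, 0, 0)    # spike, ptp 5
  d[3, 1, ] <- seq(0, 4)           # ptp 4
  d[3, 2, ] <- c(0, -2, 0, 2, 0)   # ptp 4
  EpochsSet(d, conditionLabels = c("Words", "Faces", "Cars"),
            channelTypes = c("grad", "mag"), times = (0:4) / 100,
            subjectId = "t01", session = "pre")
}

# Deterministic noise-free study configuration: every sampled quantity
# zeroed so generation is an exact function of the amplitude design.
noiselessConfig <- function(...) {
  simulationConfig(trialNoiseSd = 0, subjectSd = 0, sessionGainSd = 0,
                   conditionSd = 0, cellSd = 0, artifactRate = 0, ...)
}

# Study with planted artifacts clearly separated from clean trials.
artifactStudy <- function(nPerGroup = 2, nChannels = 5, rate = 0.1,
                          amplitude = 80, seed = 7, sfreq = 100) {
  cfg <- simulationConfig(nSubjectsPerGroup = nPerGroup,
                          nChannels = nChannels, sfreq = sfreq,
                          artifactRate = rate,
                          artifactAmplitude = amplitude, rngSeed = seed)
  simulateEpochs(cfg)
}

# Tuning-ROI weights covering both sensor types on a common scale.
bothTypeWeights <- function(epochs, scales = c(grad = 1, mag = 20)) {
  1 / scales[channelTypes(epochs)]
}

# "subject session row" keys for a set of retained-trial masks.
rejectedKeys <- function(epochsList, masks) {
  unlist(lapply(seq_along(masks), function(k) {
    e <- epochsList[[k]]
    w <- which(!masks[[k]])
    if (length(w)) paste(subjectId(e), sessionLabel(e), w)
    else character()
  }))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)) /
              max(abs(expected), .Machine$double.eps), tol)
}

# Independent naive recomputation of the full grid search.
naiveGridSearch <- function(epochsList, grid, w) {
  subs <- unique(vapply(epochsList, subjectId, character(1)))
  n1 <- length(grid[[1]]); n2 <- length(grid[[2]])
  obj <- matrix(NA_real_, n1, n2)
  ten <- matrix(TRUE, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    thr <- c(grid[[1]][i], grid[[2]][j]); names(thr) <- names(grid)
    ev <- list()
    bad <- FALSE
    for (e in epochsList) {
      ptp <- apply(epochData(e), c(1, 2), function(v) max(v) - min(v))
      keep <- sapply(seq_len(nTrials(e)), function(tr)
        all(ptp[tr, ] <= thr[channelTypes(e)]))
      if (any(tapply(keep, conditionLabels(e), sum) == 0)) {
        bad <- TRUE
        break
      }
      ww <- w / sum(w)
      course <- sapply(seq_along(epochTimes(e)), function(t)
        sum(colMeans(epochData(e)[keep, , t, drop = FALSE]) * ww))
      ev[[paste(subjectId(e), sessionLabel(e))]] <- course
    }
    if (bad) { ten[i, j] <- FALSE; next }
    rs <- sapply(subs, function(s) {
      keepT <- epochTimes(epochsList[[1]]) >= 0
      cor(ev[[paste(s, "pre")]][keepT], ev[[paste(s, "post")]][keepT])
    })
    obj[i, j] <- mean(rs)
  }
  list(objective = obj, tenable = ten)
}

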