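#' Build a group x condition x session amplitude array
#'
#' Convenience constructor for the mean evoked amplitude design of the
#' simulated trial: two intervention arms (Letter, Language), three
#' stimulus categories (Words, Faces, Cars), two sessions (pre, post).
#' All cells start at `baseline`; `lettersWordsPostBoost` adds an
#' intervention-specific enhancement to the Letter group's post-session
#' Words response — the planted-truth pattern the pipeline is designed to
#' detect.
#'
#' @param baseline common mean evoked amplitude (arbitrary units).
#' @param lettersWordsPostBoost additive enhancement of the
#'   Letter x Words x post cell.
#' @return 2 x 3 x 2 numeric array with dimnames.
#' @export
amplitudeDesign <- function(baseline = 1, lettersWordsPostBoost = 0) {
  a <- array(baseline, dim = c(2L, 3L, 2L),
             dimnames = list(group = c("Letter", "Language"),
                             condition = c("Words", "Faces", "Cars"),
                             session = c("pre", "post")))
  a["Letter", "Words", "post"] <-
    a["Letter", "Words", "post"] + lettersWordsPostBoost
  a
}

#' Configure the synthetic MEG study
#'
#' Returns a validated [SimulationConfig-class]. Defaults encode the
#' reference randomized design: 24 subjects per arm, 30 trials per
#' condition per session, 1.1 s epochs with a 100 ms pre-stimulus
#' baseline, an evoked peak at 175 ms, and two sensor types whose
#' amplitude scales differ by a factor of 20 (standing in for
#' gradiometer/magnetometer scale disparity).
#'
#' The within-subject noise decomposes into a subject x session gain
#' shared across conditions (`sessionGainSd`, the dominant term —
#' session-level signal-strength variation), a subject x condition
#' offset stable across sessions (`conditionSd`), and a residual
#' subject x session x condition jitter (`cellSd`). The total
#' within-subject SD of a condition response across sessions is
#' `sqrt(sessionGainSd^2 + cellSd^2)`; see [withinSubjectSd()].
#'
#' @param nSubjectsPerGroup,nTrialsPerCondition,nChannels design counts
#'   (channels are per sensor type).
#' @param sfreq sampling frequency, Hz.
#' @param epochSpan `c(tmin, tmax)` seconds relative to stimulus onset.
#' @param peakLatency,peakWidth Gaussian evoked kernel center and SD,
#'   seconds.
#' @param amplitudeMatrix group x condition x session mean amplitudes;
#'   see [amplitudeDesign()].
#' @param trialNoiseSd per-sample white noise SD (unit-scale channels).
#' @param subjectSd,sessionGainSd,conditionSd,cellSd amplitude
#'   random-effect SDs (see Details).
#' @param artifactRate per-trial artifact probability.
#' @param artifactAmplitude artifact transient height (unit-scale
#'   channels); must dwarf clean peak-to-peak amplitudes.
#' @param channelTypeScales named per-type amplitude multipliers.
#' @param rngSeed integer seed.
#' @return A [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nSubjectsPerGroup = 2, nChannels = 2)
#' cfg
#' @export
simulationConfig <- function(nSubjectsPerGroup = 24,
                             nTrialsPerCondition = 30,
                             nChannels = 4,
                             sfreq = 200,
                             epochSpan = c(-0.1, 1.0),
                             peakLatency = 0.175,
                             peakWidth = 0.04,
                             amplitudeMatrix = amplitudeDesign(),
                             trialNoiseSd = 1,
                             subjectSd = 0.4,
                             sessionGainSd = 0.4,
                             conditionSd = 0.2,
                             cellSd = 0.1,
                             artifactRate = 0.05,
                             artifactAmplitude = 50,
                             channelTypeScales = c(grad = 1, mag = 20),
                             rngSeed = 1) {
  new("SimulationConfig",
      nSubjectsPerGroup = nSubjectsPerGroup,
      nTrialsPerCondition = nTrialsPerCondition,
      nChannels = nChannels, sfreq = sfreq, epochSpan = epochSpan,
      peakLatency = peakLatency, peakWidth = peakWidth,
      amplitudeMatrix = amplitudeMatrix, trialNoiseSd = trialNoiseSd,
      subjectSd = subjectSd, sessionGainSd = sessionGainSd,
      conditionSd = conditionSd, cellSd = cellSd,
      artifactRate = artifactRate,
      artifactAmplitude = artifactAmplitude,
      channelTypeScales = channelTypeScales, rngSeed = rngSeed)
}

#' Total within-subject cross-session SD implied by a configuration
#'
#' The SD against which planted intervention effects are calibrated:
#' variability of a subject's condition response from one session to the
#' other, `sqrt(sessionGainSd^2 + cellSd^2)`.
#'
#' @param config a [SimulationConfig-class].
#' @return scalar SD in amplitude units.
#' @export
withinSubjectSd <- function(config) {
  sqrt(config@sessionGainSd^2 + config@cellSd^2)
}

gaussKernel <- function(times, center, width) {
  exp(-(times - center)^2 / (2 * width^2))
}

#' Simulate a full epoched MEG study with known ground truth
#'
#' Generates one [EpochsSet-class] per subject x session. Each trial is
#' the cell's evoked amplitude times a Gaussian temporal kernel centered
#' at `peakLatency`, loaded onto channels by their type scale, plus
#' i.i.d. white noise. Artifact trials additionally carry a square
#' transient of `artifactAmplitude` on a random subset (10 %) of one
#' sensor type's channels. Generation is a pure function of
#' `config@rngSeed`.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `epochs` (list of `EpochsSet`, one per
#'   subject x session) and `truth` (list: `amplitudeMatrix`,
#'   `cellAmplitudes` — the realized per-cell amplitudes including
#'   random effects, `artifactTrials` — data.frame of subject, session,
#'   condition, trial-within-condition, absolute trial row and the
#'   sensor type hit, `truePeakLatency`, `withinSubjectSd`).
#' @examples
#' sim <- simulateEpochs(simulationConfig(nSubjectsPerGroup = 1,
#'                                        nTrialsPerCondition = 2,
#'                                        nChannels = 2, sfreq = 100))
#' sim$epochs[[1]]
#' @export
simulateEpochs <- function(config) {
  validObject(config)
  set.seed(config@rngSeed)
  nG <- config@nSubjectsPerGroup
  nSub <- 2L * nG
  groups <- rep(c("Letter", "Language"), each = nG)
  subjects <- sprintf("s%02d", seq_len(nSub))
  conditions <- c("Words", "Faces", "Cars")
  sessions <- c("pre", "post")
  types <- names(config@channelTypeScales)
  chTypes <- rep(types, each = config@nChannels)
  chScale <- config@channelTypeScales[chTypes]
  nCh <- length(chTypes)
  dt <- 1 / config@sfreq
  times <- seq(config@epochSpan[1L], config@epochSpan[2L], by = dt)
  nT <- length(times)
  kern <- gaussKernel(times, config@peakLatency, config@peakWidth)
  nTr <- config@nTrialsPerCondition
  nTrialTot <- 3L * nTr

  # subject-level random effects
  bSub <- stats::rnorm(nSub, 0, config@subjectSd)
  gSess <- matrix(stats::rnorm(nSub * 2L, 0, config@sessionGainSd),
                  nSub, 2L, dimnames = list(subjects, sessions))
  oCond <- matrix(stats::rnorm(nSub * 3L, 0, config@conditionSd),
                  nSub, 3L, dimnames = list(subjects, conditions))

  epochs <- vector("list", nSub * 2L)
  artifacts <- list()
  cellAmps <- array(NA_real_, dim = c(nSub, 3L, 2L),
                    dimnames = list(subjects, conditions, sessions))
  artDur <- max(1L, round(0.1 * config@sfreq))  # 100 ms square pulse
  nArtCh <- max(1L, round(0.1 * config@nChannels))
  scaleRep <- rep(chScale, each = nTr)  # recycles over the time dim
  k <- 0L
  for (i in seq_len(nSub)) {
    for (s in sessions) {
      dat <- array(0, dim = c(nTrialTot, nCh, nT))
      condLab <- rep(conditions, each = nTr)
      for (ci in seq_along(conditions)) {
        amp <- config@amplitudeMatrix[groups[i], conditions[ci], s] +
          bSub[i] + gSess[i, s] + oCond[i, ci] +
          stats::rnorm(1L, 0, config@cellSd)
        cellAmps[i, ci, s] <- amp
        base <- outer(chScale, amp * kern)  # channels x time
        cell <- array(
          stats::rnorm(nTr * nCh * nT, 0, config@trialNoiseSd) *
            scaleRep + rep(as.vector(base), each = nTr),
          dim = c(nTr, nCh, nT))
        rows <- (ci - 1L) * nTr + seq_len(nTr)
        if (config@artifactRate > 0) {
          isArt <- which(stats::runif(nTr) < config@artifactRate)
          for (j in isArt) {
            ty <- sample(types, 1L)
            chPool <- which(chTypes == ty)
            hit <- sample(chPool, min(nArtCh, length(chPool)))
            t0 <- sample.int(nT - artDur + 1L, 1L)
            cell[j, hit, t0:(t0 + artDur - 1L)] <-
              cell[j, hit, t0:(t0 + artDur - 1L)] +
              config@artifactAmplitude * rep(chScale[hit],
                                             times = artDur)
            artifacts[[length(artifacts) + 1L]] <- data.frame(
              subject = subjects[i], session = s,
              condition = conditions[ci], trial = j, row = rows[j],
              type = ty, stringsAsFactors = FALSE)
          }
        }
        dat[rows, , ] <- cell
      }
      k <- k + 1L
      epochs[[k]] <- EpochsSet(dat, condLab, chTypes, times,
                               sfreq = config@sfreq,
                               subjectId = subjects[i], session = s,
                               group = groups[i])
    }
  }
  artifactTrials <- if (length(artifacts)) {
    do.call(rbind, artifacts)
  } else {
    data.frame(subject = character(), session = character(),
               condition = character(), trial = integer(),
               row = integer(), type = character(),
               stringsAsFactors = FALSE)
  }
  list(epochs = epochs,
       truth = list(amplitudeMatrix = config@amplitudeMatrix,
                    cellAmplitudes = cellAmps,
                    artifactTrials = artifactTrials,
                    truePeakLatency = config@peakLatency,
                    withinSubjectSd = withinSubjectSd(config)))
}

#' Simulate vertex-level ROI source time courses
#'
#' Fixture generator for the ROI aggregation stage: every vertex carries
#' the same base course up to an orientation sign and additive white
#' noise, mimicking dipole orientation flips across a cortical patch.
#'
#' @param nVertices number of vertices (>= 1).
#' @param baseCourse numeric time series shared by all vertices.
#' @param orientationSigns vector of +/-1 per vertex; recycled scalar
#'   allowed; default all +1.
#' @param noiseSd additive white noise SD.
#' @param seed RNG seed.
#' @return list with `data` (vertices x time matrix) and `flip` (the
#'   orientation sign vector).
#' @export
simulateVertexTimecourses <- function(nVertices, baseCourse,
                                      orientationSigns = 1,
                                      noiseSd = 0, seed = 1) {
  stopifnot(nVertices >= 1, is.finite(noiseSd), noiseSd >= 0)
  signs <- rep_len(orientationSigns, nVertices)
  if (!all(signs %in% c(-1, 1)))
    stop("orientationSigns must be +1 or -1")
  set.seed(seed)
  nT <- length(baseCourse)
  data <- signs %o% baseCourse +
    matrix(stats::rnorm(nVertices * nT, 0, noiseSd), nVertices, nT)
  list(data = data, flip = signs)
}

#' Simulate behavioral pre/post scores for a two-arm trial
#'
#' Long-format score table in which only the Letter (treatment) arm's
#' post-intervention scores receive `groupTimeEffect` on average,
#' mirroring a targeted intervention gain on a literacy measure.
#'
#' @param nPerGroup subjects per arm (>= 2).
#' @param baselineMean,baselineSd mean and between-subject SD of the
#'   pre-intervention score.
#' @param groupTimeEffect mean treatment x post gain.
#' @param withinSubjectSd within-subject measurement noise SD.
#' @param seed RNG seed.
#' @return data.frame with columns `subject`, `group`, `time`, `score`.
#' @export
simulateBehavioral <- function(nPerGroup, baselineMean = 10,
                               baselineSd = 3, groupTimeEffect = 0,
                               withinSubjectSd = 1, seed = 1) {
  stopifnot(nPerGroup >= 2, is.finite(withinSubjectSd),
            withinSubjectSd >= 0)
  set.seed(seed)
  nSub <- 2L * nPerGroup
  subjects <- sprintf("s%02d", seq_len(nSub))
  groups <- rep(c("Letter", "Language"), each = nPerGroup)
  intercept <- stats::rnorm(nSub, baselineMean, baselineSd)
  tab <- expand.grid(subject = subjects, time = c("pre", "post"),
                     stringsAsFactors = FALSE)
  tab$group <- groups[match(tab$subject, subjects)]
  gain <- ifelse(tab$group == "Letter" & tab$time == "post",
                 groupTimeEffect, 0)
  tab$score <- intercept[match(tab$subject, subjects)] + gain +
    stats::rnorm(nrow(tab), 0, withinSubjectSd)
  tab[order(tab$subject, factor(tab$time, c("pre", "post"))),
      c("subject", "group", "time", "score")]
}

#' Simulate a window-averaged response table directly
#'
#' Generates the long subject x condition x time response table that the
#' mixed-model stage consumes, bypassing the epoch level. Responses
#' follow `X beta` under dummy coding (references Language, Words, pre)
#' plus the same amplitude random-effect structure as
#' [simulateEpochs()]. Used for fast statistical calibration and for
#' exact coefficient-recovery checks in the zero-noise limit.
#'
#' @param nPerGroup subjects per arm.
#' @param fixef named or unnamed numeric vector of the 12 fixed-effect
#'   coefficients in `model.matrix(~ group * condition * time)` order
#'   (references Language, Words, pre); default a flat design at
#'   `baseline` with `effect` added to the Letter x Words x post cell.
#' @param baseline,effect used when `fixef` is `NULL`: common mean and
#'   Letter-arm Words post enhancement.
#' @param subjectSd,sessionGainSd,conditionSd,cellSd random-effect SDs as
#'   in [simulationConfig()].
#' @param seed RNG seed.
#' @return data.frame with columns `subject`, `group`, `condition`,
#'   `time`, `response`.
#' @export
simulateResponseTable <- function(nPerGroup, fixef = NULL, baseline = 1,
                                  effect = 0, subjectSd = 0.4,
                                  sessionGainSd = 0.4, conditionSd = 0.2,
                                  cellSd = 0.1, seed = 1) {
  stopifnot(nPerGroup >= 2)
  set.seed(seed)
  nSub <- 2L * nPerGroup
  subjects <- sprintf("s%02d", seq_len(nSub))
  groups <- rep(c("Letter", "Language"), each = nPerGroup)
  tab <- expand.grid(condition = c("Words", "Faces", "Cars"),
                     time = c("pre", "post"), subject = subjects,
                     stringsAsFactors = FALSE)
  tab$group <- groups[match(tab$subject, subjects)]
  tab <- codeFactors(tab)
  X <- stats::model.matrix(~ group * condition * time, tab)
  if (is.null(fixef)) {
    fixef <- numeric(ncol(X))
    names(fixef) <- colnames(X)
    fixef["(Intercept)"] <- baseline
    # Words-only Letter-arm post enhancement: the reference-condition
    # group:time term carries the effect and the three-way terms cancel
    # it for Faces and Cars.
    fixef["groupLetter:timepost"] <- effect
    fixef["groupLetter:conditionFaces:timepost"] <- -effect
    fixef["groupLetter:conditionCars:timepost"] <- -effect
  }
  stopifnot(length(fixef) == ncol(X))
  bSub <- stats::rnorm(nSub, 0, subjectSd)
  gSess <- matrix(stats::rnorm(nSub * 2L, 0, sessionGainSd), nSub, 2L)
  oCond <- matrix(stats::rnorm(nSub * 3L, 0, conditionSd), nSub, 3L)
  si <- match(tab$subject, subjects)
  ti <- as.integer(tab$time)
  ci <- as.integer(tab$condition)
  tab$response <- as.vector(X %*% fixef) + bSub[si] +
    gSess[cbind(si, ti)] + oCond[cbind(si, ci)] +
    stats::rnorm(nrow(tab), 0, cellSd)
  tab[, c("subject", "group", "condition", "time", "response")]
}

#' Simulate per-subject change-score time series for two groups
#'
#' Direct generator of the cluster-permutation stage's input: one change
#' time series per subject, white Gaussian noise plus (optionally) a
#' group difference confined to a time window, smoothed by the evoked
#' kernel shape.
#'
#' @param nPerGroup subjects per group.
#' @param times time grid in seconds.
#' @param effect peak group-mean difference added to group A.
#' @param effectCenter,effectWidth Gaussian profile of the planted
#'   difference (seconds); ignored when `effect = 0`.
#' @param noiseSd per-sample SD.
#' @param seed RNG seed.
#' @return list with matrices `A` and `B` (subjects x time) and `times`.
#' @export
simulateChangeSeries <- function(nPerGroup, times, effect = 0,
                                 effectCenter = 0.2, effectWidth = 0.03,
                                 noiseSd = 1, seed = 1) {
  set.seed(seed)
  nT <- length(times)
  A <- matrix(stats::rnorm(nPerGroup * nT, 0, noiseSd), nPerGroup, nT)
  B <- matrix(stats::rnorm(nPerGroup * nT, 0, noiseSd), nPerGroup, nT)
  if (effect != 0)
    A <- A + rep(effect * gaussKernel(times, effectCenter, effectWidth),
                 each = nPerGroup)
  list(A = A, B = B, times = times)
}

# Shared factor coding: references Language, Words, pre.
codeFactors <- function(tab) {
  tab$group <- factor(tab$group, levels = c("Language", "Letter"))
  tab$condition <- factor(tab$condition,
                          levels = c("Words", "Faces", "Cars"))
  tab$time <- factor(tab$time, levels = c("pre", "post"))
  tab
}
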