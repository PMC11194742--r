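#' @import methods
NULL

#' Epoched MEG data for one subject and session
#'
#' Container for trial-resolved, time-locked MEG activity: a
#' trials x channels x time array plus the per-trial condition labels,
#' per-channel sensor types, and the sampling grid. One `EpochsSet` holds
#' one subject in one session (pre- or post-intervention); a study is a
#' plain list of `EpochsSet` objects.
#'
#' @slot data numeric array, trials x channels x time.
#' @slot conditionLabels character, one stimulus category per trial
#'   (e.g. `"Words"`, `"Faces"`, `"Cars"`).
#' @slot channelTypes character, one sensor type per channel from a
#'   two-type vocabulary (e.g. `"grad"`, `"mag"`).
#' @slot times numeric, uniform strictly increasing time grid in seconds,
#'   stimulus onset at 0.
#' @slot sfreq sampling frequency in Hz.
#' @slot subjectId subject identifier.
#' @slot session `"pre"` or `"post"`.
#' @slot group intervention arm label (`"Letter"` or `"Language"`);
#'   carried for convenience, `NA` allowed.
#'
#' @seealso [EpochsSet()] for the constructor, [simulateEpochs()].
#' @export
setClass("EpochsSet",
  representation(
    data = "array",
    conditionLabels = "character",
    channelTypes = "character",
    times = "numeric",
    sfreq = "numeric",
    subjectId = "character",
    session = "character",
    group = "character"
  )
)

setValidity("EpochsSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a 3-d array (trials x channels x time)")
  else {
    if (length(object@conditionLabels) != d[1L])
      msg <- c(msg, "length(conditionLabels) must equal n_trials")
    if (length(object@channelTypes) != d[2L])
      msg <- c(msg, "length(channelTypes) must equal n_channels")
    if (length(object@times) != d[3L])
      msg <- c(msg, "length(times) must equal n_time_samples")
  }
  if (length(object@times) > 1L) {
    dt <- diff(object@times)
    if (any(dt <= 0)) msg <- c(msg, "times must be strictly increasing")
    else if (max(dt) - min(dt) > 1e-9 * max(dt))
      msg <- c(msg, "times must be a uniform grid")
  }
  if (length(object@sfreq) != 1L || !is.finite(object@sfreq) ||
      object@sfreq <= 0)
    msg <- c(msg, "sfreq must be a single positive number")
  if (length(object@session) != 1L ||
      !object@session %in% c("pre", "post"))
    msg <- c(msg, "session must be 'pre' or 'post'")
  if (length(msg)) msg else TRUE
})

#' Result of the rejection-threshold grid search
#'
#' Holds the full objective surface of the reliability-maximizing
#' threshold search: candidate peak-to-peak thresholds for each channel
#' type, the mean cross-session correlation at every tenable grid cell,
#' the tenability mask, the set of optimal cells, and the chosen
#' (most permissive optimal) threshold pair.
#'
#' @slot gridValues named list of numeric vectors, ordered candidate
#'   thresholds per channel type (first type indexes rows of `objective`).
#' @slot objective numeric matrix of mean cross-subject pre/post evoked
#'   correlations; `NA` where untenable.
#' @slot tenable logical matrix, `TRUE` where no subject x session x
#'   condition cell loses all its trials.
#' @slot retained integer matrix, total retained trials per grid cell.
#' @slot optimalCells integer matrix (one row per optimal cell, two
#'   index columns) attaining the maximum over tenable cells.
#' @slot chosen named numeric, the selected threshold per channel type.
#'
#' @seealso [tuneThresholds()], [plotGridSearch()].
#' @export
setClass("GridSearchResult",
  representation(
    gridValues = "list",
    objective = "matrix",
    tenable = "matrix",
    retained = "matrix",
    optimalCells = "matrix",
    chosen = "numeric"
  )
)

setValidity("GridSearchResult", function(object) {
  msg <- character()
  if (length(object@gridValues) != 2L)
    msg <- c(msg, "gridValues must name exactly two channel types")
  ob <- object@objective[object@tenable]
  ob <- ob[!is.na(ob)]
  if (length(ob) && (min(ob) < -1 - 1e-12 || max(ob) > 1 + 1e-12))
    msg <- c(msg, "tenable objective values must lie in [-1, 1]")
  if (any(!is.na(object@objective[!object@tenable])))
    msg <- c(msg, "untenable cells must carry no objective value")
  if (length(msg)) msg else TRUE
})

#' Analysis time window around an evoked peak
#'
#' A closed interval `[start, end]` on the epoch time axis, normally
#' defined as +/- 50 ms around the first peak of the grand-average
#' waveform.
#'
#' @slot peakLatency peak latency in seconds.
#' @slot start window start in seconds (inclusive).
#' @slot end window end in seconds (inclusive).
#'
#' @seealso [defineWindow()], [findFirstPeak()], [windowMean()].
#' @export
setClass("TimeWindow",
  representation(peakLatency = "numeric", start = "numeric",
                 end = "numeric")
)

setValidity("TimeWindow", function(object) {
  msg <- character()
  if (!(length(object@start) == 1L && length(object@end) == 1L &&
        length(object@peakLatency) == 1L))
    msg <- c(msg, "peakLatency, start, end must be scalars")
  else {
    if (!all(is.finite(c(object@start, object@end, object@peakLatency))))
      msg <- c(msg, "window bounds must be finite")
    else {
      if (object@end <= object@start)
        msg <- c(msg, "end must exceed start")
      if (object@peakLatency < object@start ||
          object@peakLatency > object@end)
        msg <- c(msg, "peakLatency must lie inside the window")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Aggregated ROI evoked time courses for a study
#'
#' One aggregated evoked time series per subject x session x condition,
#' stored as a row-aligned metadata table plus a course matrix sharing a
#' single time grid.
#'
#' @slot meta data.frame with columns `subject`, `group`, `session`,
#'   `condition`; one row per course.
#' @slot courses numeric matrix, rows aligned with `meta`, columns are
#'   time samples.
#' @slot times numeric time grid in seconds.
#'
#' @seealso [extractTimecourses()], [windowMeans()], [changeSeries()].
#' @export
setClass("ROITimecourseSet",
  representation(meta = "data.frame", courses = "matrix",
                 times = "numeric")
)

setValidity("ROITimecourseSet", function(object) {
  msg <- character()
  need <- c("subject", "group", "session", "condition")
  if (!all(need %in% names(object@meta)))
    msg <- c(msg, sprintf("meta must have columns %s",
                          paste(need, collapse = ", ")))
  if (nrow(object@meta) != nrow(object@courses))
    msg <- c(msg, "meta and courses must have the same number of rows")
  if (ncol(object@courses) != length(object@times))
    msg <- c(msg, "courses columns must match times")
  if (nrow(object@courses) && !all(is.finite(object@courses)))
    msg <- c(msg, "courses must be finite")
  if (length(msg)) msg else TRUE
})

#' Temporal cluster-based permutation test result
#'
#' Maximal supra-threshold runs of the pointwise two-sample t course
#' comparing intervention-driven change between groups, with cluster mass
#' statistics and max-mass permutation p-values.
#'
#' @slot clusters data.frame with columns `start`, `end` (seconds,
#'   inclusive sample times), `mass`, `p`, `sign`.
#' @slot tCourse observed pointwise t statistic per time sample.
#' @slot times time grid (seconds) the test ran on.
#' @slot threshold cluster-forming |t| threshold.
#' @slot nPermutations number of random label permutations (0 when the
#'   null was enumerated exhaustively).
#' @slot seed RNG seed used for the permutations.
#'
#' @seealso [permutationTest()].
#' @export
setClass("ClusterResult",
  representation(
    clusters = "data.frame",
    tCourse = "numeric",
    times = "numeric",
    threshold = "numeric",
    nPermutations = "numeric",
    seed = "numeric"
  )
)

setValidity("ClusterResult", function(object) {
  msg <- character()
  cl <- object@clusters
  need <- c("start", "end", "mass", "p", "sign")
  if (!all(need %in% names(cl)))
    msg <- c(msg, sprintf("clusters must have columns %s",
                          paste(need, collapse = ", ")))
  else if (nrow(cl)) {
    if (any(cl$p <= 0 | cl$p > 1))
      msg <- c(msg, "cluster p-values must lie in (0, 1]")
    if (any(sign(cl$mass) != cl$sign))
      msg <- c(msg, "mass sign must match cluster sign")
  }
  if (length(object@tCourse) != length(object@times))
    msg <- c(msg, "tCourse and times must have equal length")
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic MEG study generator
#'
#' Design constants and noise parameters of the simulated randomized
#' controlled trial: two intervention arms measured pre and post on three
#' stimulus categories. Defaults reproduce the reference design: 24
#' subjects per arm, 30 trials per condition and session, a single evoked
#' peak at 175 ms, and two sensor types on very different amplitude
#' scales.
#'
#' @slot nSubjectsPerGroup subjects per intervention arm.
#' @slot nTrialsPerCondition trials per condition per session.
#' @slot nChannels channels per sensor type.
#' @slot sfreq sampling frequency, Hz.
#' @slot epochSpan epoch limits in seconds, `c(tmin, tmax)`.
#' @slot peakLatency evoked peak latency, seconds.
#' @slot peakWidth Gaussian kernel SD, seconds.
#' @slot amplitudeMatrix numeric group x condition x session array of
#'   mean evoked amplitudes (arbitrary units), dimnames
#'   `Letter`/`Language`, `Words`/`Faces`/`Cars`, `pre`/`post`.
#' @slot trialNoiseSd per-sample white noise SD (before channel scaling).
#' @slot subjectSd SD of the subject-level amplitude intercept.
#' @slot sessionGainSd SD of the subject x session gain offset shared
#'   across conditions (session-level signal-strength variation).
#' @slot conditionSd SD of the subject x condition amplitude offset
#'   (stable across sessions).
#' @slot cellSd SD of the subject x session x condition residual
#'   amplitude jitter.
#' @slot artifactRate per-trial probability of an artifact transient.
#' @slot artifactAmplitude amplitude of the artifact square transient
#'   (before channel scaling).
#' @slot channelTypeScales named numeric, per-type amplitude multiplier.
#' @slot rngSeed integer seed making generation fully deterministic.
#'
#' @seealso [simulationConfig()], [simulateEpochs()].
#' @export
setClass("SimulationConfig",
  representation(
    nSubjectsPerGroup = "numeric",
    nTrialsPerCondition = "numeric",
    nChannels = "numeric",
    sfreq = "numeric",
    epochSpan = "numeric",
    peakLatency = "numeric",
    peakWidth = "numeric",
    amplitudeMatrix = "array",
    trialNoiseSd = "numeric",
    subjectSd = "numeric",
    sessionGainSd = "numeric",
    conditionSd = "numeric",
    cellSd = "numeric",
    artifactRate = "numeric",
    artifactAmplitude = "numeric",
    channelTypeScales = "numeric",
    rngSeed = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  cnt <- c(nSubjectsPerGroup = object@nSubjectsPerGroup,
           nTrialsPerCondition = object@nTrialsPerCondition,
           nChannels = object@nChannels)
  bad <- cnt < 1 | cnt != round(cnt)
  if (any(bad))
    msg <- c(msg, sprintf("counts must be integers >= 1: %s",
                          paste(names(cnt)[bad], collapse = ", ")))
  if (object@artifactRate < 0 || object@artifactRate > 1)
    msg <- c(msg, "artifactRate must lie in [0, 1]")
  sds <- c(object@trialNoiseSd, object@subjectSd, object@sessionGainSd,
           object@conditionSd, object@cellSd)
  if (any(!is.finite(sds)) || any(sds < 0))
    msg <- c(msg, "noise SDs must be finite and non-negative")
  if (!is.finite(object@peakWidth) || object@peakWidth <= 0)
    msg <- c(msg, "peakWidth must be finite and positive")
  if (length(object@epochSpan) != 2L ||
      object@epochSpan[2L] <= object@epochSpan[1L])
    msg <- c(msg, "epochSpan must be c(tmin, tmax) with tmax > tmin")
  else if (object@peakLatency < object@epochSpan[1L] ||
           object@peakLatency > object@epochSpan[2L])
    msg <- c(msg, "epochSpan must contain peakLatency")
  dm <- dim(object@amplitudeMatrix)
  if (length(dm) != 3L || !all(dm == c(2L, 3L, 2L)))
    msg <- c(msg, "amplitudeMatrix must be 2 x 3 x 2 (group x condition x session)")
  if (length(object@channelTypeScales) != 2L ||
      is.null(names(object@channelTypeScales)))
    msg <- c(msg, "channelTypeScales must be a named vector of two types")
  if (length(msg)) msg else TRUE
})
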