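#' SVD-based ROI time-course aggregation with sign flipping
#'
#' Collapses a vertices x time array to a single time course: the first
#' right-singular vector of the data, scaled to match the mean
#' per-vertex power (`||S||_2 / sqrt(n_vertices)` where `||S||_2` is
#' the vector norm of all singular values, i.e. the Frobenius norm of
#' the data) and sign-flipped to the dominant source orientation (sign
#' of the inner product between the first left-singular vector and the
#' orientation flip vector).
#'
#' @param data numeric matrix, vertices x time (or a list with elements
#'   `data` and `flip` as returned by [simulateVertexTimecourses()]).
#' @param flip vector of +/-1 orientation signs per vertex; default all
#'   +1.
#' @return numeric time course of length `ncol(data)`; all-zero input
#'   yields an all-zero course.
#' @examples
#' x <- sin(seq(0, pi, length.out = 40))
#' v <- rbind(x, x, x)
#' all.equal(svdFlipAggregate(v), x)
#' @export
svdFlipAggregate <- function(data, flip = NULL) {
  if (is.list(data) && !is.null(data$data)) {
    if (is.null(flip)) flip <- data$flip
    data <- data$data
  }
  data <- as.matrix(data)
  nv <- nrow(data)
  stopifnot(nv >= 1L)
  if (is.null(flip)) flip <- rep(1, nv)
  stopifnot(length(flip) == nv, all(flip %in% c(-1, 1)))
  if (all(data == 0)) return(numeric(ncol(data)))
  s <- svd(data)
  scale <- sqrt(sum(s$d^2)) / sqrt(nv)
  sgn <- sign(sum(s$u[, 1L] * flip))
  if (sgn == 0) sgn <- 1
  sgn * scale * s$v[, 1L]
}

#' First peak of a grand-average waveform
#'
#' Latency of the earliest local maximum within the search range whose
#' topographic prominence exceeds a floor (a fraction of the waveform's
#' range within the search window). The first — not the largest —
#' qualifying peak is returned, on the sampling grid.
#'
#' @param grandAverage numeric time series (mean over subjects and
#'   conditions).
#' @param times time grid in seconds.
#' @param searchRange `c(tmin, tmax)` seconds; default 50-500 ms
#'   post-stimulus.
#' @param prominenceFrac prominence floor as a fraction of the
#'   grand-average range inside the search window.
#' @return peak latency in seconds.
#' @export
findFirstPeak <- function(grandAverage, times,
                          searchRange = c(0.05, 0.5),
                          prominenceFrac = 0.1) {
  stopifnot(length(grandAverage) == length(times))
  inWin <- which(times >= searchRange[1L] & times <= searchRange[2L])
  if (length(inWin) < 3L)
    stop("search range contains fewer than 3 samples")
  x <- grandAverage
  floorP <- prominenceFrac * diff(range(x[inWin]))
  # candidate local maxima on the full series, filtered to the window
  n <- length(x)
  isMax <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] &
                     x[2:(n - 1)] >= x[3:n], FALSE)
  cands <- which(isMax)
  cands <- cands[cands %in% inWin]
  for (p in cands) {
    # prominence: drop to the highest minimum separating this peak from
    # a higher one (or the series end) on each side
    left <- if (p > 1L) {
      higher <- which(x[1:(p - 1L)] > x[p])
      lo <- if (length(higher)) (max(higher) + 1L) else 1L
      min(x[lo:(p - 1L)])
    } else x[p]
    right <- if (p < n) {
      higher <- which(x[(p + 1L):n] > x[p])
      hi <- if (length(higher)) (p + min(higher) - 1L) else n
      min(x[(p + 1L):hi])
    } else x[p]
    prom <- x[p] - max(left, right)
    if (prom >= floorP) return(times[p])
  }
  stop("no qualifying peak in [", searchRange[1L], ", ",
       searchRange[2L], "] s; widen the search range or lower the ",
       "prominence floor")
}

#' Define the analysis window around a peak
#'
#' Closed interval of +/- `halfWidth` (default 50 ms) around the peak
#' latency, e.g. a 175 ms peak yields 125-225 ms and a 185 ms peak
#' yields 135-235 ms.
#'
#' @param peakLatency peak latency in seconds.
#' @param halfWidth half window width in seconds.
#' @param epochSpan optional `c(tmin, tmax)`; the window must fit
#'   inside it.
#' @return A [TimeWindow-class].
#' @export
defineWindow <- function(peakLatency, halfWidth = 0.05,
                         epochSpan = NULL) {
  w <- new("TimeWindow", peakLatency = peakLatency,
           start = peakLatency - halfWidth,
           end = peakLatency + halfWidth)
  if (!is.null(epochSpan) &&
      (w@start < epochSpan[1L] || w@end > epochSpan[2L]))
    stop(sprintf("window [%.3f, %.3f] s exceeds the epoch span [%.3f, %.3f] s",
                 w@start, w@end, epochSpan[1L], epochSpan[2L]))
  w
}

#' Mean response within a time window
#'
#' Arithmetic mean of the samples with `start <= t <= end` (closed
#' interval, nearest-sample grid snapping by inclusion).
#'
#' @param course numeric time series.
#' @param times time grid in seconds.
#' @param window a [TimeWindow-class].
#' @return scalar mean response.
#' @export
windowMean <- function(course, times, window) {
  stopifnot(length(course) == length(times))
  # snap window edges to the grid: tolerate float error far below the
  # sampling step so on-grid endpoints are always included
  tol <- if (length(times) > 1L) (times[2L] - times[1L]) * 1e-6 else 0
  keep <- times >= window@start - tol & times <= window@end + tol
  if (!any(keep)) stop("no time samples fall inside the window")
  mean(course[keep])
}

#' Extract aggregated evoked ROI time courses per subject, session and
#' condition
#'
#' For every epochs set and condition: average the retained trials into
#' an evoked channels x time array, restrict to the analysis-ROI
#' channels, and collapse channels to one course — either by
#' [svdFlipAggregate()] (the analysis-ROI convention) or by an
#' unweighted mean (the tuning-ROI convention).
#'
#' @param allEpochs list of [EpochsSet-class].
#' @param retainedMasks optional list of logical retained-trial masks
#'   aligned with `allEpochs` (from [applyRejection()]); default keep
#'   all trials.
#' @param roiChannels optional integer/logical channel selector for the
#'   ROI; default the channels of the first sensor type present.
#' @param aggregate `"svd"` or `"mean"`.
#' @return A [ROITimecourseSet-class].
#' @export
extractTimecourses <- function(allEpochs, retainedMasks = NULL,
                               roiChannels = NULL,
                               aggregate = c("svd", "mean")) {
  aggregate <- match.arg(aggregate)
  times <- epochTimes(allEpochs[[1L]])
  meta <- list()
  rows <- list()
  for (k in seq_along(allEpochs)) {
    e <- allEpochs[[k]]
    sel <- roiChannels
    if (is.null(sel)) sel <- e@channelTypes == e@channelTypes[1L]
    keep <- if (is.null(retainedMasks)) rep(TRUE, nTrials(e))
            else retainedMasks[[k]]
    for (cond in unique(e@conditionLabels)) {
      tri <- which(e@conditionLabels == cond & keep)
      if (!length(tri))
        stop("no retained trials for ", e@subjectId, "/", e@session,
             "/", cond)
      ev <- colMeans(e@data[tri, , , drop = FALSE], dims = 1L)
      ev <- ev[sel, , drop = FALSE]
      course <- if (aggregate == "svd") svdFlipAggregate(ev)
                else colMeans(ev)
      meta[[length(meta) + 1L]] <- data.frame(
        subject = e@subjectId, group = e@group, session = e@session,
        condition = cond, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- course
    }
  }
  new("ROITimecourseSet", meta = do.call(rbind, meta),
      courses = do.call(rbind, rows), times = times)
}

#' Grand-average waveform over courses
#'
#' Mean time course over (a subset of) the rows of a
#' [ROITimecourseSet-class]; by default only pre-intervention courses
#' are pooled so that the analysis window is defined without reference
#' to post-intervention effects.
#'
#' @param tcs a [ROITimecourseSet-class].
#' @param sessions sessions to pool (`"pre"`, `"post"` or both).
#' @return numeric time course.
#' @export
grandAverage <- function(tcs, sessions = "pre") {
  keep <- tcs@meta$session %in% sessions
  if (!any(keep)) stop("no courses in the requested session(s)")
  colMeans(tcs@courses[keep, , drop = FALSE])
}

#' Window-averaged response table
#'
#' Applies [windowMean()] to every course, yielding the long response
#' table the mixed-model stage consumes.
#'
#' @param tcs a [ROITimecourseSet-class].
#' @param window a [TimeWindow-class].
#' @return data.frame with columns `subject`, `group`, `condition`,
#'   `time` (session relabelled), `response`.
#' @export
windowMeans <- function(tcs, window) {
  resp <- apply(tcs@courses, 1L, windowMean, times = tcs@times,
                window = window)
  out <- tcs@meta
  out$time <- out$session
  out$session <- NULL
  out$response <- resp
  out[, c("subject", "group", "condition", "time", "response")]
}
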