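#' Construct an EpochsSet
#'
#' @param data trials x channels x time numeric array.
#' @param conditionLabels character vector, one label per trial.
#' @param channelTypes character vector, one sensor type per channel.
#' @param times time grid in seconds.
#' @param sfreq sampling frequency in Hz; derived from `times` when
#'   omitted.
#' @param subjectId subject identifier.
#' @param session `"pre"` or `"post"`.
#' @param group intervention arm label, `NA` when unknown.
#'
#' @return A validated [EpochsSet-class] object.
#' @examples
#' x <- EpochsSet(array(0, c(2, 3, 4)), rep("Words", 2),
#'                c("grad", "grad", "mag"), times = (0:3) / 100,
#'                subjectId = "s01", session = "pre")
#' nTrials(x)
#' @export
EpochsSet <- function(data, conditionLabels, channelTypes, times,
                      sfreq = NULL, subjectId = "s01", session = "pre",
                      group = NA_character_) {
  if (is.null(sfreq)) {
    sfreq <- if (length(times) > 1L) 1 / mean(diff(times)) else 1
  }
  new("EpochsSet", data = data,
      conditionLabels = as.character(conditionLabels),
      channelTypes = as.character(channelTypes),
      times = as.numeric(times), sfreq = sfreq,
      subjectId = as.character(subjectId), session = session,
      group = as.character(group))
}

#' @rdname EpochsSet
#' @param x an `EpochsSet`.
#' @export
nTrials <- function(x) dim(x@data)[1L]

#' @rdname EpochsSet
#' @export
nChannels <- function(x) dim(x@data)[2L]

#' @rdname EpochsSet
#' @export
epochData <- function(x) x@data

#' @rdname EpochsSet
#' @export
conditionLabels <- function(x) x@conditionLabels

#' @rdname EpochsSet
#' @export
channelTypes <- function(x) x@channelTypes

#' @rdname EpochsSet
#' @export
epochTimes <- function(x) x@times

#' @rdname EpochsSet
#' @export
samplingRate <- function(x) x@sfreq

#' @rdname EpochsSet
#' @export
subjectId <- function(x) x@subjectId

#' @rdname EpochsSet
#' @export
sessionLabel <- function(x) x@session

#' @rdname EpochsSet
#' @export
groupLabel <- function(x) x@group

setMethod("show", "EpochsSet", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EpochsSet: subject %s, session %s%s\n  %d trials x %d channels x %d samples (%.0f Hz, %.3f..%.3f s)\n",
    object@subjectId, object@session,
    if (is.na(object@group)) "" else paste0(" (", object@group, ")"),
    d[1L], d[2L], d[3L], object@sfreq,
    min(object@times), max(object@times)))
  cat("  conditions:",
      paste(sprintf("%s=%d", names(table(object@conditionLabels)),
                    table(object@conditionLabels)), collapse = ", "),
      "\n")
  cat("  channel types:",
      paste(sprintf("%s=%d", names(table(object@channelTypes)),
                    table(object@channelTypes)), collapse = ", "), "\n")
})

setMethod("show", "GridSearchResult", function(object) {
  cat(sprintf(
    "GridSearchResult: %d x %d grid (%s), %d tenable cell(s)\n",
    nrow(object@objective), ncol(object@objective),
    paste(names(object@gridValues), collapse = " x "),
    sum(object@tenable)))
  cat(sprintf("  best objective: %.4f at %d optimal cell(s)\n",
              max(object@objective[object@tenable], na.rm = TRUE),
              nrow(object@optimalCells)))
  cat("  chosen thresholds:",
      paste(sprintf("%s=%.4g", names(object@chosen), object@chosen),
            collapse = ", "), "\n")
})

setMethod("show", "TimeWindow", function(object) {
  cat(sprintf(
    "TimeWindow: peak %.0f ms, window [%.0f, %.0f] ms (closed)\n",
    1000 * object@peakLatency, 1000 * object@start, 1000 * object@end))
})

setMethod("show", "ROITimecourseSet", function(object) {
  cat(sprintf(
    "ROITimecourseSet: %d courses (%d subjects), %d time samples\n",
    nrow(object@meta), length(unique(object@meta$subject)),
    length(object@times)))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf(
    "ClusterResult: |t| threshold %.3f, %s permutations\n",
    object@threshold,
    if (object@nPermutations > 0) format(object@nPermutations)
    else "exhaustive"))
  if (nrow(object@clusters)) {
    cl <- object@clusters
    for (i in seq_len(nrow(cl)))
      cat(sprintf("  %+d cluster %.0f-%.0f ms, mass %.2f, p = %.4g\n",
                  cl$sign[i], 1000 * cl$start[i], 1000 * cl$end[i],
                  cl$mass[i], cl$p[i]))
  } else cat("  no supra-threshold clusters\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d subjects/group, %d trials/condition, %d+%d channels, %.0f Hz\n",
    object@nSubjectsPerGroup, object@nTrialsPerCondition,
    object@nChannels, object@nChannels, object@sfreq))
  cat(sprintf("  peak %.0f ms (sd %.0f ms); artifact rate %.2f; seed %d\n",
              1000 * object@peakLatency, 1000 * object@peakWidth,
              object@artifactRate, object@rngSeed))
})

#' Accessors for grid-search results
#'
#' @param x a [GridSearchResult-class].
#' @return `chosenThresholds`: named numeric thresholds;
#'   `searchObjective`: the objective matrix; `tenableMask`: the logical
#'   tenability matrix; `gridValues`: the candidate threshold lists.
#' @export
chosenThresholds <- function(x) x@chosen

#' @rdname chosenThresholds
#' @export
searchObjective <- function(x) x@objective

#' @rdname chosenThresholds
#' @export
tenableMask <- function(x) x@tenable

#' @rdname chosenThresholds
#' @export
gridValues <- function(x) x@gridValues

#' Accessors for cluster results
#'
#' @param x a [ClusterResult-class].
#' @return `clusterTable`: data.frame of clusters; `observedTCourse`:
#'   the pointwise t statistic time series.
#' @export
clusterTable <- function(x) x@clusters

#' @rdname clusterTable
#' @export
observedTCourse <- function(x) x@tCourse

#' Accessors for ROI time-course sets
#'
#' @param x a [ROITimecourseSet-class].
#' @return `courseMeta`: the metadata data.frame; `courseMatrix`: the
#'   course matrix; `courseTimes`: the time grid.
#' @export
courseMeta <- function(x) x@meta

#' @rdname courseMeta
#' @export
courseMatrix <- function(x) x@courses

#' @rdname courseMeta
#' @export
courseTimes <- function(x) x@times

#' Accessors for time windows
#'
#' @param x a [TimeWindow-class].
#' @return `windowStart`/`windowEnd`/`windowPeak`: scalar seconds.
#' @export
windowStart <- function(x) x@start

#' @rdname windowStart
#' @export
windowEnd <- function(x) x@end

#' @rdname windowStart
#' @export
windowPeak <- function(x) x@peakLatency
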