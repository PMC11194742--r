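#' Per-trial, per-channel peak-to-peak amplitudes
#'
#' The rejection statistic: for every trial and channel, the maximum
#' minus the minimum of the signal over the epoch's time samples.
#'
#' @param epochs an [EpochsSet-class].
#' @return numeric matrix, trials x channels, non-negative.
#' @export
peakToPeak <- function(epochs) {
  d <- dim(epochs@data)
  if (d[3L] < 1L) stop("epoch has an empty time axis")
  m <- epochs@data
  dim(m) <- c(d[1L] * d[2L], d[3L])
  hi <- m[, 1L]
  lo <- m[, 1L]
  for (t in seq_len(d[3L])[-1L]) {
    hi <- pmax(hi, m[, t])
    lo <- pmin(lo, m[, t])
  }
  matrix(hi - lo, d[1L], d[2L])
}

#' Apply peak-to-peak rejection thresholds
#'
#' A trial is rejected iff any channel's peak-to-peak amplitude exceeds
#' the threshold for that channel's sensor type; `Inf` means "never
#' reject" for a type.
#'
#' @param epochs an [EpochsSet-class].
#' @param thresholds named numeric vector, one positive threshold per
#'   channel type present in `epochs`.
#' @param ptp optional precomputed [peakToPeak()] matrix.
#' @return logical vector of length `nTrials(epochs)`, `TRUE` for
#'   retained trials.
#' @export
applyRejection <- function(epochs, thresholds, ptp = NULL) {
  types <- unique(epochs@channelTypes)
  if (any(!types %in% names(thresholds)))
    stop("no threshold for channel type(s): ",
         paste(setdiff(types, names(thresholds)), collapse = ", "))
  if (any(!is.finite(thresholds[types]) & thresholds[types] != Inf) ||
      any(thresholds[types] < 0))
    stop("thresholds must be non-negative (or +Inf)")
  if (is.null(ptp)) ptp <- peakToPeak(epochs)
  thrCh <- thresholds[epochs@channelTypes]
  over <- sweep(ptp, 2L, thrCh, ">")
  rowSums(over) == 0L
}

#' Mean cross-session evoked reliability
#'
#' The rejection-tuning objective: per-subject Pearson correlation
#' between the pre- and post-session evoked ROI time courses, averaged
#' across subjects. Subjects with a zero-variance course in either
#' session are excluded with a warning.
#'
#' @param preCourses,postCourses subjects x time matrices on the same
#'   subject ordering and time grid.
#' @param times optional time grid in seconds; when supplied, only
#'   post-stimulus samples (`t >= 0`) enter the correlation.
#' @return scalar in `[-1, 1]` (`NA` if no subject is usable).
#' @export
reliabilityObjective <- function(preCourses, postCourses, times = NULL) {
  stopifnot(all(dim(preCourses) == dim(postCourses)))
  if (!is.null(times)) {
    keep <- times >= 0
    preCourses <- preCourses[, keep, drop = FALSE]
    postCourses <- postCourses[, keep, drop = FALSE]
  }
  n <- nrow(preCourses)
  r <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- preCourses[i, ]
    b <- postCourses[i, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    r[i] <- stats::cor(a, b)
  }
  if (anyNA(r))
    warning(sum(is.na(r)),
            " subject(s) with zero-variance evoked course excluded ",
            "from the reliability objective")
  mean(r, na.rm = TRUE)
}

#' Log-spaced candidate threshold grids from the data
#'
#' Candidate rejection thresholds per sensor type: log-spaced values
#' spanning the 50th to 100th percentile of the pooled pre-rejection
#' peak-to-peak amplitude distribution of that type, across all
#' subjects, sessions and trials.
#'
#' @param allEpochs list of [EpochsSet-class] objects.
#' @param nPerType number of candidates per type.
#' @return named list of increasing numeric vectors, one per type.
#' @export
makeThresholdGrid <- function(allEpochs, nPerType = 5) {
  types <- unique(unlist(lapply(allEpochs, channelTypes)))
  pooled <- lapply(types, function(ty) {
    unlist(lapply(allEpochs, function(e) {
      ptp <- peakToPeak(e)
      as.vector(ptp[, e@channelTypes == ty, drop = FALSE])
    }))
  })
  names(pooled) <- types
  lapply(pooled, function(v) {
    qs <- stats::quantile(v, c(0.5, 1), names = FALSE)
    exp(seq(log(qs[1L]), log(qs[2L]), length.out = nPerType))
  })
}

#' Reliability-maximizing grid search over rejection thresholds
#'
#' For every pair of candidate thresholds (one per sensor type), applies
#' rejection to every subject and session, marks the cell untenable if
#' any subject x session x condition loses all its trials, and otherwise
#' scores the cell by the mean cross-subject correlation between pre-
#' and post-session grand-average evoked responses in the tuning ROI
#' (trials pooled across conditions). The chosen pair is the most
#' permissive cell among those attaining the maximum: ties broken by
#' total retained-trial count, then by the first type's threshold, then
#' the second's.
#'
#' @param allEpochs list of [EpochsSet-class]; every subject must appear
#'   in both sessions.
#' @param gridByType named list of two increasing candidate-threshold
#'   vectors (one per sensor type); default [makeThresholdGrid()].
#' @param roiWeights optional numeric channel weights defining the
#'   tuning ROI; default an unweighted mean over the channels of the
#'   first sensor type present.
#' @return A [GridSearchResult-class].
#' @seealso [plotGridSearch()], [applyRejection()].
#' @export
tuneThresholds <- function(allEpochs, gridByType = NULL,
                           roiWeights = NULL) {
  subjects <- vapply(allEpochs, subjectId, character(1L))
  sessions <- vapply(allEpochs, sessionLabel, character(1L))
  subs <- unique(subjects)
  for (s in subs) {
    if (!all(c("pre", "post") %in% sessions[subjects == s]))
      stop("subject ", s, " is missing a session")
  }
  if (is.null(gridByType)) gridByType <- makeThresholdGrid(allEpochs)
  if (length(gridByType) != 2L || is.null(names(gridByType)) ||
      any(lengths(gridByType) == 0L))
    stop("gridByType must be a named list of two non-empty grids")
  types <- names(gridByType)

  # Precompute, per epochs set: ptp matrix and the per-trial tuning-ROI
  # course (weighted channel mean), so grid cells only re-average.
  prep <- lapply(allEpochs, function(e) {
    w <- roiWeights
    if (is.null(w)) {
      w <- as.numeric(e@channelTypes == types[1L])
    }
    stopifnot(length(w) == nChannels(e))
    w <- w / sum(w)
    d <- dim(e@data)
    # trials x time course: weighted channel mean
    tc <- matrix(matrix(aperm(e@data, c(1L, 3L, 2L)),
                        ncol = d[2L]) %*% w, d[1L], d[3L])
    list(ptp = peakToPeak(e), course = tc, cond = e@conditionLabels,
         types = e@channelTypes, subject = e@subjectId,
         session = e@session, times = e@times)
  })
  times <- prep[[1L]]$times

  n1 <- length(gridByType[[1L]])
  n2 <- length(gridByType[[2L]])
  objective <- matrix(NA_real_, n1, n2)
  tenable <- matrix(TRUE, n1, n2)
  retained <- matrix(0L, n1, n2)
  firstOffender <- NULL

  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      thr <- c(gridByType[[1L]][i], gridByType[[2L]][j])
      names(thr) <- types
      pre <- matrix(NA_real_, length(subs), length(times))
      post <- matrix(NA_real_, length(subs), length(times))
      nKept <- 0L
      ok <- TRUE
      for (p in prep) {
        thrCh <- thr[p$types]
        keep <- rowSums(sweep(p$ptp, 2L, thrCh, ">")) == 0L
        byCond <- tapply(keep, p$cond, sum)
        if (any(byCond == 0L)) {
          ok <- FALSE
          if (is.null(firstOffender))
            firstOffender <- sprintf(
              "%s/%s/%s", p$subject, p$session,
              names(byCond)[which(byCond == 0L)[1L]])
          break
        }
        nKept <- nKept + sum(keep)
        ev <- colMeans(p$course[keep, , drop = FALSE])
        si <- match(p$subject, subs)
        if (p$session == "pre") pre[si, ] <- ev else post[si, ] <- ev
      }
      if (!ok) {
        tenable[i, j] <- FALSE
        next
      }
      retained[i, j] <- nKept
      objective[i, j] <- reliabilityObjective(pre, post, times)
    }
  }
  if (!any(tenable))
    stop("every grid cell is untenable; first offending cell: ",
         firstOffender)

  best <- max(objective[tenable], na.rm = TRUE)
  cand <- which(tenable & !is.na(objective) &
                  abs(objective - best) < 1e-12, arr.ind = TRUE)
  # most permissive optimal cell: retained count, then threshold 1, 2
  score <- cbind(retained[cand], gridByType[[1L]][cand[, 1L]],
                 gridByType[[2L]][cand[, 2L]])
  o <- order(score[, 1L], score[, 2L], score[, 3L], decreasing = TRUE)
  pick <- cand[o[1L], , drop = TRUE]
  chosen <- c(gridByType[[1L]][pick[1L]], gridByType[[2L]][pick[2L]])
  names(chosen) <- types
  new("GridSearchResult", gridValues = gridByType,
      objective = objective, tenable = tenable, retained = retained,
      optimalCells = unname(cand), chosen = chosen)
}

#' Heatmap of the rejection-threshold grid search
#'
#' Objective matrix as an image with untenable cells in pale gray and
#' the optimal cell(s) outlined.
#'
#' @param result a [GridSearchResult-class].
#' @param ... passed to [graphics::image()].
#' @return invisibly, `result`.
#' @export
plotGridSearch <- function(result, ...) {
  n1 <- nrow(result@objective)
  n2 <- ncol(result@objective)
  z <- result@objective
  graphics::image(seq_len(n1), seq_len(n2), z,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = paste(names(result@gridValues)[1L],
                               "threshold index"),
                  ylab = paste(names(result@gridValues)[2L],
                               "threshold index"),
                  main = "Mean cross-session evoked reliability", ...)
  bad <- which(!result@tenable, arr.ind = TRUE)
  if (nrow(bad))
    graphics::rect(bad[, 1L] - 0.5, bad[, 2L] - 0.5,
                   bad[, 1L] + 0.5, bad[, 2L] + 0.5,
                   col = "gray85", border = NA)
  oc <- result@optimalCells
  graphics::rect(oc[, 1L] - 0.5, oc[, 2L] - 0.5, oc[, 1L] + 0.5,
                 oc[, 2L] + 0.5, border = "red", lwd = 2)
  invisible(result)
}
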