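#' Pointwise two-sample t statistic time course
#'
#' Independent-samples pooled-variance t at every time sample, comparing
#' per-subject change time series between two groups. Samples with zero
#' pooled variance get t = 0 (with a warning): they cannot seed
#' clusters.
#'
#' @param A,B numeric matrices, subjects x time, same number of
#'   columns; at least two subjects per group.
#' @return numeric t time course of length `ncol(A)`.
#' @export
pointwiseT <- function(A, B) {
  stopifnot(ncol(A) == ncol(B), nrow(A) >= 2L, nrow(B) >= 2L)
  nA <- nrow(A)
  nB <- nrow(B)
  mA <- colMeans(A)
  mB <- colMeans(B)
  vA <- colSums(sweep(A, 2L, mA)^2) / (nA - 1)
  vB <- colSums(sweep(B, 2L, mB)^2) / (nB - 1)
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  t <- (mA - mB) / se
  if (any(se == 0)) {
    warning(sum(se == 0), " sample(s) with zero pooled variance; t set to 0")
    t[se == 0] <- 0
  }
  t
}

# Masses (sum of t) of maximal supra-threshold runs; `flag` marks the
# run membership, `tv` the statistic course.
runMasses <- function(flag, tv) {
  if (!any(flag)) {
    return(data.frame(startIdx = integer(), endIdx = integer(),
                      mass = numeric()))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    startIdx = starts[keep], endIdx = ends[keep],
    mass = vapply(keep, function(i) sum(tv[starts[i]:ends[i]]),
                  numeric(1L)))
}

#' Candidate temporal clusters of a t course
#'
#' Maximal contiguous runs with `t > threshold` (positive clusters) or
#' `t < -threshold` (negative clusters); the cluster mass is the sum of
#' t over the run.
#'
#' @param tCourse numeric t statistic per time sample.
#' @param threshold positive cluster-forming threshold.
#' @return data.frame with columns `startIdx`, `endIdx` (inclusive
#'   sample indices), `mass`, `sign`, ordered by start.
#' @export
formClusters <- function(tCourse, threshold) {
  stopifnot(threshold > 0)
  pos <- runMasses(tCourse > threshold, tCourse)
  neg <- runMasses(tCourse < -threshold, tCourse)
  pos$sign <- rep(1L, nrow(pos))
  neg$sign <- rep(-1L, nrow(neg))
  out <- rbind(pos, neg)
  out[order(out$startIdx), , drop = FALSE]
}

# tolerance for comparing a null max-mass against an observed mass:
# ties recomputed through a different arithmetic path must count as >=
massTol <- function(m) 1e-8 * max(1, abs(m))

maxAbsMass <- function(tCourse, threshold) {
  m <- c(runMasses(tCourse > threshold, tCourse)$mass,
         runMasses(tCourse < -threshold, tCourse)$mass)
  if (length(m)) max(abs(m)) else 0
}

# t courses for many label permutations at once. X is the stacked
# (nA + nB) x time matrix; `aIdx` a list of index vectors for
# pseudo-group A. Returns a length(aIdx) x time matrix of t values
# (zero pooled variance -> 0).
permTCourses <- function(X, aIdx, nA, nB) {
  n <- nA + nB
  P <- matrix(0, length(aIdx), n)
  for (i in seq_along(aIdx)) P[i, aIdx[[i]]] <- 1
  X2 <- X^2
  totS <- colSums(X)
  totS2 <- colSums(X2)
  SA <- P %*% X
  SA2 <- P %*% X2
  SB <- sweep(-SA, 2L, totS, "+")
  SB2 <- sweep(-SA2, 2L, totS2, "+")
  mA <- SA / nA
  mB <- SB / nB
  ssA <- SA2 - nA * mA^2
  ssB <- SB2 - nB * mB^2
  sp2 <- (ssA + ssB) / (nA + nB - 2)
  se <- sqrt(pmax(sp2, 0) * (1 / nA + 1 / nB))
  t <- (mA - mB) / se
  t[!is.finite(t)] <- 0
  t
}

#' Temporal cluster-based permutation test between two groups
#'
#' Compares intervention-driven change time courses between groups with
#' the max-mass permutation procedure: pointwise two-sample t, maximal
#' supra-threshold runs scored by their t mass, and a null distribution
#' of the maximum absolute cluster mass under random reassignment of
#' subjects to groups (group sizes preserved). Two-sided by
#' construction (the null pools both signs). Each cluster's p-value is
#' `(1 + #(null >= |mass|)) / (1 + n_permutations)`, so p is never
#' zero; with `method = "exhaustive"` all label splits are enumerated
#' and p is the exact proportion.
#'
#' @param A,B subjects x time change-score matrices for the two groups.
#' @param times optional time grid in seconds; with `tRange`, restricts
#'   the tested samples (default 0-500 ms when `times` is given).
#' @param threshold cluster-forming |t| threshold; default the
#'   two-sided p < 0.05 t quantile at `nrow(A) + nrow(B) - 2` df.
#' @param nPermutations number of random permutations (>= 99).
#' @param seed RNG seed for the permutations.
#' @param tRange `c(tmin, tmax)` in seconds, used when `times` given.
#' @param method `"montecarlo"` or `"exhaustive"` (enumerates all
#'   `choose(nA + nB, nA)` splits; only sensible for small samples).
#' @return A [ClusterResult-class].
#' @export
permutationTest <- function(A, B, times = NULL, threshold = NULL,
                            nPermutations = 1024, seed = 0,
                            tRange = c(0, 0.5),
                            method = c("montecarlo", "exhaustive")) {
  method <- match.arg(method)
  stopifnot(ncol(A) == ncol(B))
  if (!is.null(times)) {
    stopifnot(length(times) == ncol(A))
    keep <- times >= tRange[1L] & times <= tRange[2L]
    A <- A[, keep, drop = FALSE]
    B <- B[, keep, drop = FALSE]
    times <- times[keep]
  } else {
    times <- seq_len(ncol(A)) - 1
  }
  nA <- nrow(A)
  nB <- nrow(B)
  if (is.null(threshold))
    threshold <- stats::qt(0.975, nA + nB - 2)
  tObs <- suppressWarnings(pointwiseT(A, B))
  clusters <- formClusters(tObs, threshold)

  X <- rbind(A, B)
  n <- nA + nB
  if (method == "exhaustive") {
    splits <- utils::combn(n, nA, simplify = FALSE)
    tNull <- permTCourses(X, splits, nA, nB)
    null <- apply(tNull, 1L, maxAbsMass, threshold = threshold)
    pfun <- function(m) mean(null >= abs(m) - massTol(m))
    nPerm <- 0
  } else {
    stopifnot(nPermutations >= 99)
    set.seed(seed)
    aIdx <- lapply(seq_len(nPermutations),
                   function(i) sample.int(n, nA))
    tNull <- permTCourses(X, aIdx, nA, nB)
    null <- apply(tNull, 1L, maxAbsMass, threshold = threshold)
    pfun <- function(m)
      (1 + sum(null >= abs(m) - massTol(m))) / (1 + nPermutations)
    nPerm <- nPermutations
  }
  tab <- data.frame(start = times[clusters$startIdx],
                    end = times[clusters$endIdx],
                    mass = clusters$mass,
                    p = if (nrow(clusters))
                          vapply(clusters$mass, pfun, numeric(1L))
                        else numeric(),
                    sign = clusters$sign)
  new("ClusterResult", clusters = tab, tCourse = tObs, times = times,
      threshold = threshold, nPermutations = nPerm, seed = seed)
}

#' Per-subject change-score contrast series
#'
#' Builds the cluster test's input from ROI time courses: for each
#' subject, the post-minus-pre change in a condition contrast (e.g.
#' `(Words - Cars)_post - (Words - Cars)_pre`), split by intervention
#' group.
#'
#' @param tcs a [ROITimecourseSet-class] with both sessions.
#' @param condA,condB the contrasted conditions (`condA - condB`);
#'   `condB = NULL` uses the raw condition course.
#' @return list of subjects x time matrices, one per group (`Letter`,
#'   `Language`), plus `times`.
#' @export
changeSeries <- function(tcs, condA = "Words", condB = "Cars") {
  meta <- tcs@meta
  out <- list()
  for (g in c("Letter", "Language")) {
    subs <- unique(meta$subject[meta$group == g])
    rows <- t(vapply(subs, function(s) {
      one <- function(session, cond) {
        i <- which(meta$subject == s & meta$session == session &
                     meta$condition == cond)
        if (length(i) != 1L)
          stop("missing course for ", s, "/", session, "/", cond)
        tcs@courses[i, ]
      }
      contrast <- function(session) {
        if (is.null(condB)) one(session, condA)
        else one(session, condA) - one(session, condB)
      }
      contrast("post") - contrast("pre")
    }, numeric(length(tcs@times))))
    out[[g]] <- rows
  }
  out$times <- tcs@times
  out
}
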