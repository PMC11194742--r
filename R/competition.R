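#' Per-subject change table of window-averaged responses
#'
#' Post-minus-pre change in the window-averaged response for every
#' condition, one row per subject — the input to the competition
#' (change-coupling) correlations. Subjects missing a session for any
#' condition are dropped with a warning.
#'
#' @param responses long response table (columns `subject`, `group`,
#'   `condition`, `time`, `response`) as produced by [windowMeans()];
#'   alternatively a [ROITimecourseSet-class], in which case `window`
#'   must be supplied and window means are computed first.
#' @param window a [TimeWindow-class]; only used for time-course input.
#' @return data.frame with columns `subject`, `group`, `dWords`,
#'   `dFaces`, `dCars`.
#' @export
changeTable <- function(responses, window = NULL) {
  if (is(responses, "ROITimecourseSet")) {
    if (is.null(window))
      stop("a TimeWindow is required for time-course input")
    responses <- windowMeans(responses, window)
  }
  tab <- checkTable(responses,
                    c("subject", "group", "condition", "time",
                      "response"))
  out <- list()
  dropped <- character()
  for (s in unique(tab$subject)) {
    sub <- tab[tab$subject == s, ]
    d <- vapply(c("Words", "Faces", "Cars"), function(cond) {
      pre <- sub$response[sub$condition == cond & sub$time == "pre"]
      post <- sub$response[sub$condition == cond & sub$time == "post"]
      if (length(pre) != 1L || length(post) != 1L) NA_real_
      else post - pre
    }, numeric(1L))
    if (anyNA(d)) {
      dropped <- c(dropped, s)
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      subject = s, group = sub$group[1L], dWords = d[["Words"]],
      dFaces = d[["Faces"]], dCars = d[["Cars"]],
      stringsAsFactors = FALSE)
  }
  if (length(dropped))
    warning("dropped subject(s) missing a session: ",
            paste(dropped, collapse = ", "))
  do.call(rbind, out)
}

#' Competition correlation between change in Words and another category
#'
#' Pearson correlation between the per-subject change in the Words
#' response and the change in another category's response, with the
#' two-sided p-value from the exact t transform of r. A negative
#' correlation is the competition signature: word gains coupled to
#' face/object losses. A positive correlation indicates shared gain
#' (e.g. session-level signal strength or alertness).
#'
#' @param table a change table from [changeTable()].
#' @param other `"Cars"` or `"Faces"`.
#' @param subset `"all"` (both arms) or `"letter"` (Letter arm only).
#' @return list with `r`, `p`, `n`, `other`, `subset`.
#' @export
changeCorrelation <- function(table, other = c("Cars", "Faces"),
                              subset = c("all", "letter")) {
  other <- match.arg(other)
  subset <- match.arg(subset)
  if (subset == "letter") table <- table[table$group == "Letter", ]
  n <- nrow(table)
  if (n < 3L) stop("need at least 3 subjects after subsetting")
  x <- table$dWords
  y <- if (other == "Cars") table$dCars else table$dFaces
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a change column")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, other = other,
       subset = subset)
}
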