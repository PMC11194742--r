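#' @importFrom lme4 lmerControl isSingular
#' @importFrom lmerTest lmer
NULL

# Fit a mixed model down a convergence fallback ladder of random-effect
# structures. Fixed-effect coding never changes; only the random
# structure is simplified, and every step is recorded. The last rung is
# a fixed-effects-only lm(), used when the mixed model is degenerate
# (e.g. zero residual variance).
fitLadder <- function(fixedRhs, reTerms, data) {
  log <- character()
  for (re in reTerms) {
    form <- stats::as.formula(paste("response ~", fixedRhs, "+", re))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lmerTest::lmer(form, data = data,
                       control = lme4::lmerControl(
                         check.conv.singular = "ignore",
                         calc.derivs = FALSE)))),
      error = function(e) e)
    if (inherits(fit, "error")) {
      log <- c(log, sprintf("random structure '%s' failed: %s", re,
                            conditionMessage(fit)))
      next
    }
    msgs <- fit@optinfo$conv$lme4$messages
    if (any(grepl("failed to converge", msgs))) {
      log <- c(log, sprintf("random structure '%s' did not converge", re))
      next
    }
    if (lme4::isSingular(fit))
      log <- c(log, sprintf("random structure '%s': singular fit (kept)",
                            re))
    return(list(fit = fit, structure = re, log = log, mixed = TRUE))
  }
  form <- stats::as.formula(paste("response ~", fixedRhs))
  fit <- stats::lm(form, data = data)
  log <- c(log, "fell back to fixed-effects-only least squares")
  list(fit = fit, structure = "none (OLS)", log = log, mixed = FALSE)
}

# Coefficient and F tables on a common layout for lmerTest and lm fits.
lmeTables <- function(fitted) {
  if (fitted$mixed) {
    co <- stats::coef(summary(fitted$fit, ddf = "Satterthwaite"))
    coefs <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                        se = co[, "Std. Error"], df = co[, "df"],
                        t = co[, "t value"], p = co[, "Pr(>|t|)"],
                        row.names = NULL, stringsAsFactors = FALSE)
    an <- stats::anova(fitted$fit, ddf = "Satterthwaite")
    Ftab <- data.frame(term = rownames(an), numDf = an$NumDF,
                       denDf = an$DenDF, F = an$`F value`,
                       p = an$`Pr(>F)`, row.names = NULL,
                       stringsAsFactors = FALSE)
  } else {
    co <- stats::coef(summary(fitted$fit))
    rdf <- stats::df.residual(fitted$fit)
    coefs <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                        se = co[, "Std. Error"], df = rdf,
                        t = co[, "t value"], p = co[, "Pr(>|t|)"],
                        row.names = NULL, stringsAsFactors = FALSE)
    an <- stats::anova(fitted$fit)
    keep <- rownames(an) != "Residuals"
    Ftab <- data.frame(term = rownames(an)[keep],
                       numDf = an$Df[keep], denDf = rdf,
                       F = an$`F value`[keep], p = an$`Pr(>F)`[keep],
                       row.names = NULL, stringsAsFactors = FALSE)
  }
  list(coefficients = coefs, F = Ftab)
}

newLMEResult <- function(fitted, tables, extra = list()) {
  structure(c(list(coefficients = tables$coefficients,
                   F = tables$F,
                   randomStructure = fitted$structure,
                   convergence = if (length(fitted$log)) fitted$log
                                 else "converged at the full structure",
                   fit = fitted$fit),
              extra),
            class = "LMEResult")
}

#' @export
print.LMEResult <- function(x, ...) {
  cat("Linear mixed-effects result\n")
  cat("  random structure:", x$randomStructure, "\n")
  cat("  convergence:", paste(x$convergence, collapse = "; "), "\n")
  if (!is.null(x$F) && nrow(x$F)) {
    cat("  F tests:\n")
    print(format(x$F, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

checkTable <- function(tab, needCols) {
  miss <- setdiff(needCols, names(tab))
  if (length(miss))
    stop("response table is missing column(s): ",
         paste(miss, collapse = ", "))
  tab
}

#' Three-way intervention x condition x time mixed model
#'
#' The trial's primary neural test: fixed effects of group, condition
#' and time with all interactions (dummy coded against the Language
#' arm, Words and pre references) and per-subject random intercepts and
#' slopes for all within-subject effects (condition, time and their
#' interaction). Reports the omnibus three-way interaction F with
#' Satterthwaite denominator df and the Words-vs-Cars and Words-vs-Faces
#' three-way t statistics. Non-convergent random structures fall down a
#' recorded simplification ladder (correlated slopes, additive slopes,
#' time-only, intercept-only, fixed-effects-only).
#'
#' @param table data.frame with columns `subject`, `group`,
#'   `condition`, `time`, `response`.
#' @param reCorrelated logical; keep correlations among random effects
#'   (default) or force them independent.
#' @return An `LMEResult` list: `coefficients`, `F`, `interactionF`
#'   (the three-way row), `tWordsCars`, `tWordsFaces`,
#'   `randomStructure`, `convergence`, `fit`.
#' @export
fitThreeWay <- function(table, reCorrelated = TRUE) {
  tab <- codeFactors(checkTable(
    table, c("subject", "group", "condition", "time", "response")))
  if (length(unique(tab$time)) < 2L)
    stop("both pre and post measurements are required")
  bar <- if (reCorrelated) "|" else "||"
  ladder <- c(sprintf("(1 + condition * time %s subject)", bar),
              sprintf("(1 + condition + time %s subject)", bar),
              sprintf("(1 + time %s subject)", bar),
              "(1 | subject)")
  fitted <- fitLadder("group * condition * time", ladder, tab)
  tables <- lmeTables(fitted)
  co <- tables$coefficients
  getRow <- function(term) co[co$term == term, , drop = FALSE]
  Frow <- tables$F[tables$F$term == "group:condition:time", ,
                   drop = FALSE]
  newLMEResult(fitted, tables, list(
    interactionF = Frow,
    tWordsCars = getRow("groupLetter:conditionCars:timepost"),
    tWordsFaces = getRow("groupLetter:conditionFaces:timepost")))
}

#' Group x time mixed model for one measure or condition
#'
#' The behavioral-outcome model (and the single-condition neural change
#' model): fixed group, time and group x time effects with per-subject
#' random intercept and time slope. Also refits time-only models within
#' each arm to report intervention-driven growth separately per group.
#'
#' @param table data.frame with columns `subject`, `group`, `time` and
#'   `response` (a `score` column is accepted and renamed).
#' @param withinGroups also fit the per-arm time-only models (skippable
#'   when only the interaction is of interest, e.g. in simulation
#'   loops).
#' @return An `LMEResult` list; `tInteraction` holds the group x time
#'   row and `withinGroup` a data.frame of per-arm time slopes.
#' @export
fitGroupByTime <- function(table, withinGroups = TRUE) {
  if (!"response" %in% names(table) && "score" %in% names(table))
    names(table)[names(table) == "score"] <- "response"
  tab <- checkTable(table, c("subject", "group", "time", "response"))
  tab$condition <- NULL
  tab <- codeFactors(cbind(tab, condition = "Words"))
  ladder <- c("(1 + time | subject)", "(1 | subject)")
  fitted <- fitLadder("group * time", ladder, tab)
  tables <- lmeTables(fitted)
  co <- tables$coefficients
  inter <- co[co$term == "groupLetter:timepost", , drop = FALSE]
  within <- NULL
  if (withinGroups) {
    within <- do.call(rbind, lapply(levels(tab$group), function(g) {
      sub <- tab[tab$group == g, ]
      f <- fitLadder("time", ladder, sub)
      tb <- lmeTables(f)$coefficients
      row <- tb[tb$term == "timepost", , drop = FALSE]
      cbind(group = g, row)
    }))
  }
  newLMEResult(fitted, tables, list(
    tInteraction = inter, withinGroup = within))
}

#' Condition x group mixed model at a single time point
#'
#' Category-selectivity model fit separately to the pre- or
#' post-intervention data: fixed condition, group and condition x group
#' effects with a per-subject random intercept (each subject contributes
#' one response per condition). Reports the condition, group and
#' interaction F tests plus the pairwise group-difference t's for the
#' Words-Cars and Words-Faces contrasts.
#'
#' @param table data.frame with columns `subject`, `group`, `condition`,
#'   `response`, all at one time point (a `time` column, if present,
#'   must be constant).
#' @return An `LMEResult` list with `conditionF`, `groupF`,
#'   `interactionF`, `tWordsCars`, `tWordsFaces`.
#' @export
fitConditionByGroup <- function(table) {
  tab <- checkTable(table,
                    c("subject", "group", "condition", "response"))
  if ("time" %in% names(tab) && length(unique(tab$time)) > 1L)
    stop("table must contain a single time point")
  tab$time <- "pre"
  tab <- codeFactors(tab)
  fitted <- fitLadder("condition * group", "(1 | subject)", tab)
  tables <- lmeTables(fitted)
  co <- tables$coefficients
  Ft <- tables$F
  getF <- function(term) Ft[Ft$term == term, , drop = FALSE]
  newLMEResult(fitted, tables, list(
    conditionF = getF("condition"),
    groupF = getF("group"),
    interactionF = getF("condition:group"),
    tWordsCars = co[co$term == "conditionCars:groupLetter", ,
                    drop = FALSE],
    tWordsFaces = co[co$term == "conditionFaces:groupLetter", ,
                     drop = FALSE]))
}

#' Cohen's d from two group summaries
#'
#' Standardized mean difference with the equal-n pooled SD convention
#' `sqrt((sd1^2 + sd2^2) / 2)`. For example, group means 1.770
#' (SD 0.262) and 0.657 (SD 0.214) give d = 4.65.
#'
#' @param mean1,sd1,mean2,sd2 group summaries; SDs must be positive.
#' @return scalar effect size.
#' @export
cohensD <- function(mean1, sd1, mean2, sd2) {
  stopifnot(is.finite(sd1), is.finite(sd2), sd1 >= 0, sd2 >= 0)
  pooled <- sqrt((sd1^2 + sd2^2) / 2)
  if (pooled == 0) stop("pooled SD is zero")
  (mean1 - mean2) / pooled
}

#' Power of a two-sided two-sample t-test
#'
#' Exact power from the noncentral t distribution with noncentrality
#' `d * sqrt(n / 2)` and `2n - 2` degrees of freedom.
#'
#' @param d true standardized effect size (Cohen's d).
#' @param nPerGroup sample size per group (>= 2).
#' @param alpha two-sided significance level.
#' @return power in `[0, 1]`.
#' @examples
#' tTestPower(4.65, 20)   # > 0.95
#' tTestPower(0, 20)      # = alpha
#' @export
tTestPower <- function(d, nPerGroup, alpha = 0.05) {
  stopifnot(nPerGroup >= 2, alpha > 0, alpha < 1, is.finite(d))
  df <- 2 * nPerGroup - 2
  ncp <- d * sqrt(nPerGroup / 2)
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp)
}
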