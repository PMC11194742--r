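#' Configure an end-to-end study analysis
#'
#' Bundles everything [runPipeline()] needs: the synthetic-study
#' configuration (or a directory of epochs JSON files), the rejection
#' grid size, the window mode, and the cluster-test parameters. Seeds
#' are recorded in every output.
#'
#' @param simulation a [SimulationConfig-class]; ignored when
#'   `epochsDir` is given.
#' @param epochsDir optional directory of `*.json` epochs files to
#'   analyze instead of simulating.
#' @param gridSize candidate thresholds per sensor type for
#'   [makeThresholdGrid()].
#' @param windowMode `"auto"` (data-driven peak +/- 50 ms from the
#'   pre-intervention grand average) or a numeric `c(start, end)` in
#'   seconds.
#' @param clusterNPerm permutations for the cluster tests.
#' @param clusterThreshold cluster-forming |t| threshold; `NULL` for
#'   the two-sided p < 0.05 t quantile.
#' @param seed master seed; the cluster stage derives its permutation
#'   seed from it.
#' @param outDir optional directory; when set, [runPipeline()] writes
#'   the result bundle and stage artifacts there.
#' @return a `StudyConfig` list.
#' @export
studyConfig <- function(simulation = simulationConfig(),
                        epochsDir = NULL, gridSize = 3,
                        windowMode = "auto", clusterNPerm = 1024,
                        clusterThreshold = NULL, seed = 1,
                        outDir = NULL) {
  structure(list(simulation = simulation, epochsDir = epochsDir,
                 gridSize = gridSize, windowMode = windowMode,
                 clusterNPerm = clusterNPerm,
                 clusterThreshold = clusterThreshold, seed = seed,
                 outDir = outDir),
            class = "StudyConfig")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

rowAsList <- function(row, cols) {
  if (is.null(row) || nrow(row) == 0L)
    return(stats::setNames(as.list(rep(NA_real_, length(cols))), cols))
  out <- as.list(row[1L, cols])
  names(out) <- cols
  out
}

clusterSummary <- function(cr) {
  list(threshold = cr@threshold, nPermutations = cr@nPermutations,
       clusters = cr@clusters)
}

#' Run the full analysis pipeline on one study
#'
#' Sequences every stage on one (simulated or loaded) study:
#' reliability-maximizing rejection tuning, trial rejection, SVD ROI
#' time-course extraction, data-driven window definition, the three-way
#' group x condition x time mixed model, the Words group x time change
#' model, pre/post condition-by-group models, temporal cluster
#' permutation tests on the Words-Cars and Words-Faces change
#' contrasts, and the competition correlations. Returns a result
#' bundle carrying the seed and a configuration hash; identical
#' configurations reproduce identical bundles.
#'
#' @param config a `StudyConfig` from [studyConfig()].
#' @param verbose emit stage-boundary messages with trial-retention
#'   counts.
#' @return a named list (`provenance`, `tuning`, `retention`,
#'   `window`, `threeWay`, `wordsGroupByTime`, `conditionByGroup`,
#'   `clusters`, `competition`).
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "StudyConfig"))
  say <- function(...) if (verbose) message(...)

  sim <- NULL
  if (is.null(config$epochsDir)) {
    simCfg <- config$simulation
    simCfg@rngSeed <- config$seed
    sim <- stage("simulate", simulateEpochs(simCfg))
    epochs <- sim$epochs
  } else {
    files <- sort(list.files(config$epochsDir, "\\.json$",
                             full.names = TRUE))
    if (!length(files)) stop("no epochs files in ", config$epochsDir)
    epochs <- stage("read", lapply(files, readEpochs))
  }
  say("loaded ", length(epochs), " subject-session epoch sets")

  grid <- stage("tune", makeThresholdGrid(epochs, config$gridSize))
  tuning <- stage("tune", tuneThresholds(epochs, grid))
  thr <- chosenThresholds(tuning)
  say("chosen thresholds: ",
      paste(sprintf("%s=%.4g", names(thr), thr), collapse = ", "))

  masks <- stage("reject", lapply(epochs, applyRejection,
                                  thresholds = thr))
  retention <- stage("reject", do.call(rbind, lapply(
    seq_along(epochs), function(k) {
      e <- epochs[[k]]
      kept <- tapply(masks[[k]], e@conditionLabels, sum)
      data.frame(subject = e@subjectId, session = e@session,
                 condition = names(kept),
                 retained = as.integer(kept),
                 total = as.integer(table(e@conditionLabels)[names(kept)]),
                 row.names = NULL, stringsAsFactors = FALSE)
    })))
  say("trial retention: ", sum(retention$retained), "/",
      sum(retention$total))

  tcs <- stage("extract",
               extractTimecourses(epochs, masks, aggregate = "svd"))

  window <- stage("window", {
    if (identical(config$windowMode, "auto")) {
      ga <- grandAverage(tcs, sessions = "pre")
      peak <- findFirstPeak(ga, courseTimes(tcs))
      defineWindow(peak, epochSpan = range(courseTimes(tcs)))
    } else {
      w <- as.numeric(config$windowMode)
      new("TimeWindow", peakLatency = mean(w), start = w[1L],
          end = w[2L])
    }
  })
  say(sprintf("analysis window: %.0f-%.0f ms", 1000 * window@start,
              1000 * window@end))

  responses <- stage("window", windowMeans(tcs, window))

  threeWay <- stage("stats", fitThreeWay(responses))
  wordsGBT <- stage("stats", fitGroupByTime(
    responses[responses$condition == "Words", ]))
  cbgPre <- stage("stats", fitConditionByGroup(
    responses[responses$time == "pre",
              c("subject", "group", "condition", "response")]))
  cbgPost <- stage("stats", fitConditionByGroup(
    responses[responses$time == "post",
              c("subject", "group", "condition", "response")]))

  clSeed <- config$seed + 1000L
  clWC <- stage("cluster", {
    cs <- changeSeries(tcs, "Words", "Cars")
    permutationTest(cs$Letter, cs$Language, times = cs$times,
                    threshold = config$clusterThreshold,
                    nPermutations = config$clusterNPerm, seed = clSeed)
  })
  clWF <- stage("cluster", {
    cs <- changeSeries(tcs, "Words", "Faces")
    permutationTest(cs$Letter, cs$Language, times = cs$times,
                    threshold = config$clusterThreshold,
                    nPermutations = config$clusterNPerm, seed = clSeed)
  })

  competition <- stage("correlate", {
    ct <- changeTable(responses)
    out <- list()
    for (other in c("Cars", "Faces"))
      for (ss in c("all", "letter"))
        out[[paste0(tolower(other), "_", ss)]] <-
          changeCorrelation(ct, other, ss)
    out
  })

  cfgForHash <- config
  cfgForHash$outDir <- NULL
  bundle <- list(
    provenance = list(seed = config$seed,
                      configHash = configHash(unclass(cfgForHash)),
                      package = as.character(
                        utils::packageVersion("megrct"))),
    tuning = list(chosen = as.list(thr),
                  bestObjective = max(searchObjective(tuning)[
                    tenableMask(tuning)], na.rm = TRUE),
                  nTenable = sum(tenableMask(tuning)),
                  gridValues = gridValues(tuning)),
    retention = retention,
    window = list(peak = window@peakLatency, start = window@start,
                  end = window@end),
    threeWay = list(
      interaction = rowAsList(threeWay$interactionF,
                              c("numDf", "denDf", "F", "p")),
      tWordsCars = rowAsList(threeWay$tWordsCars,
                             c("estimate", "df", "t", "p")),
      tWordsFaces = rowAsList(threeWay$tWordsFaces,
                              c("estimate", "df", "t", "p")),
      randomStructure = threeWay$randomStructure,
      convergence = threeWay$convergence),
    wordsGroupByTime = list(
      interaction = rowAsList(wordsGBT$tInteraction,
                              c("estimate", "df", "t", "p")),
      withinGroup = wordsGBT$withinGroup),
    conditionByGroup = list(
      pre = list(condition = rowAsList(cbgPre$conditionF,
                                       c("numDf", "denDf", "F", "p")),
                 interaction = rowAsList(cbgPre$interactionF,
                                         c("numDf", "denDf", "F", "p"))),
      post = list(condition = rowAsList(cbgPost$conditionF,
                                        c("numDf", "denDf", "F", "p")),
                  interaction = rowAsList(cbgPost$interactionF,
                                          c("numDf", "denDf", "F",
                                            "p")))),
    clusters = list(wordsCars = clusterSummary(clWC),
                    wordsFaces = clusterSummary(clWF)),
    competition = competition)
  if (!is.null(sim))
    bundle$groundTruth <- list(
      truePeakLatency = sim$truth$truePeakLatency,
      withinSubjectSd = sim$truth$withinSubjectSd,
      nArtifactTrials = nrow(sim$truth$artifactTrials))

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    writeResultJson(bundle, file.path(config$outDir, "results.json"))
    utils::write.csv(responses,
                     file.path(config$outDir, "responses.csv"),
                     row.names = FALSE)
    utils::write.csv(retention,
                     file.path(config$outDir, "retention.csv"),
                     row.names = FALSE)
  }
  bundle
}
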