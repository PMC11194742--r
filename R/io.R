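#' Write and read epoched data as portable JSON
#'
#' Serializes an [EpochsSet-class] to a self-describing JSON layout:
#' the flattened `data` vector with its `dim`, the `times` grid,
#' `sfreq`, `subject`, `session`, `group`, and the `condition_labels`
#' and `channel_types` arrays. Numbers are written at full precision so
#' the round trip is lossless.
#'
#' @param epochs an [EpochsSet-class].
#' @param path file path.
#' @return `writeEpochs`: invisibly, `path`; `readEpochs`: the
#'   reconstructed `EpochsSet`.
#' @export
writeEpochs <- function(epochs, path) {
  obj <- list(
    format = "megrct-epochs-1",
    subject = epochs@subjectId,
    session = epochs@session,
    group = epochs@group,
    sfreq = epochs@sfreq,
    times = epochs@times,
    condition_labels = epochs@conditionLabels,
    channel_types = epochs@channelTypes,
    dim = dim(epochs@data),
    data = as.vector(epochs@data))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeEpochs
#' @export
readEpochs <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("subject", "session", "sfreq", "times", "condition_labels",
            "channel_types", "dim", "data")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("epochs file ", path, " is missing field(s): ",
         paste(miss, collapse = ", "))
  data <- array(obj$data, dim = obj$dim)
  EpochsSet(data, obj$condition_labels, obj$channel_types, obj$times,
            sfreq = obj$sfreq, subjectId = obj$subject,
            session = obj$session,
            group = if (is.null(obj$group)) NA_character_ else obj$group)
}

#' Write a result object as reproducible JSON
#'
#' Full-precision JSON so that repeated runs with the same seeds produce
#' byte-identical files.
#'
#' @param x a list (result bundle, grid-search summary, ...).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeResultJson <- function(x, path) {
  jsonlite::write_json(x, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Stable hash of a configuration object
#'
#' MD5 of the canonical JSON serialization; embedded in every result
#' bundle for provenance.
#'
#' @param x any jsonlite-serializable object.
#' @return hex digest string.
#' @export
configHash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, digits = I(17), auto_unbox = TRUE,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Read a study configuration from YAML
#'
#' Maps a YAML file onto [studyConfig()] arguments; unknown keys are an
#' error, simulation parameters go through [simulationConfig()].
#'
#' @param path YAML file path.
#' @return a `StudyConfig` list (see [studyConfig()]).
#' @export
readStudyConfig <- function(path) {
  y <- yaml::read_yaml(path)
  simArgs <- y$simulation
  y$simulation <- NULL
  known <- names(formals(studyConfig))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!is.null(simArgs))
    y$simulation <- do.call(simulationConfig, simArgs)
  do.call(studyConfig, y)
}
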