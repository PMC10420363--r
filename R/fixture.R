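## Portable plain-text dataset fixture.
##
## A single versioned JSON document holding every trial (markers, events,
## metadata) and the optional partition map, so test datasets round-trip
## without any binary dependency.

FIXTURE_SCHEMA <- "gaitevents-fixture"
FIXTURE_VERSION <- 1L

#' Write a dataset to a JSON fixture
#'
#' Lossless (up to decimal representation) serialization of a
#' `gait_dataset` including pathology labels and the partition map.
#'
#' @param dataset a `gait_dataset`.
#' @param path output file path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
write_fixture <- function(dataset, path) {
  validate_dataset(dataset)
  doc <- list(
    schema = FIXTURE_SCHEMA,
    version = FIXTURE_VERSION,
    trials = lapply(unname(dataset$trials), function(tr) {
      list(trial_id = tr$trial_id, subject_id = tr$subject_id,
           pathology = tr$pathology, fs = tr$fs,
           markers = lapply(tr$markers, function(m) {
             dimnames(m) <- NULL
             m
           }),
           events = tr$events)
    }),
    partition = as.list(dataset$partition)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a dataset from a JSON fixture
#'
#' @param path fixture path written by [write_fixture()].
#' @return a `gait_dataset`.
#' @export
read_fixture <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, FIXTURE_SCHEMA)) {
    stop_fmt("not a %s fixture: %s", FIXTURE_SCHEMA, path)
  }
  if (!identical(as.integer(doc$version), FIXTURE_VERSION)) {
    stop_fmt("fixture schema version %s not supported (expected %d)",
             doc$version, FIXTURE_VERSION)
  }
  trials <- lapply(seq_len(nrow(doc$trials)), function(i) {
    row <- doc$trials[i, ]
    mk_df <- row$markers
    markers <- lapply(stats::setNames(nm = names(mk_df)), function(nm) {
      m <- mk_df[[nm]][[1L]]
      colnames(m) <- AXIS_NAMES
      m
    })
    ev <- row$events[[1L]]
    events <- if (is.data.frame(ev) && nrow(ev)) {
      gait_events(ev$etype, ev$side, ev$frame, ev$source)
    } else {
      gait_events()
    }
    gait_trial(markers, fs = row$fs, events = events, trial_id = row$trial_id,
               subject_id = row$subject_id, pathology = row$pathology)
  })
  partition <- if (length(doc$partition)) unlist(doc$partition) else NULL
  gait_dataset(trials, partition = partition)
}
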