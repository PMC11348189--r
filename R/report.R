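REPORT_SCHEMA <- "capscan-report/1"

#' Write the screening report
#'
#' Emits a flat TSV with one row per folding event and a self-describing,
#' schema-versioned JSON document with the state fractions and geometry
#' scalars, plus (optionally) a TSV of per-member secondary-structure tracks.
#'
#' @param events a `cap_events` data.frame from [detect_folding_events()].
#' @param states a `cap_states` from [classify_states()], or `NULL`.
#' @param geometry named list of geometry scalars (e.g. from the pipeline's
#'   geometry stage), or `NULL`.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @param ss_tracks optional named character vector of per-member secondary
#'   structure strings.
#' @return named list of the files written, invisibly.
#' @export
write_report <- function(events, states = NULL, geometry = NULL,
                         dir = ".", prefix = "capscan", ss_tracks = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) cap_stop("capscan_io_error", "cannot create directory %s", dir)
  }
  tsv <- file.path(dir, paste0(prefix, "_events.tsv"))
  json <- file.path(dir, paste0(prefix, "_report.json"))
  tryCatch({
    write.table(as.data.frame(events), tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }, error = function(e) cap_stop("capscan_io_error", "cannot write %s: %s",
                                  tsv, conditionMessage(e)))
  payload <- list(
    schema = REPORT_SCHEMA,
    package_version = as.character(utils::packageVersion("capscan")),
    n_events = nrow(events),
    events = as.data.frame(events))
  if (!is.null(states))
    payload$states <- list(fractions = as.list(states$fractions),
                           displacement_threshold = states$displacement_threshold,
                           labels = states$labels)
  if (!is.null(geometry)) payload$geometry <- geometry
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  files <- list(events_tsv = tsv, report_json = json)
  if (!is.null(ss_tracks)) {
    trk <- file.path(dir, paste0(prefix, "_ss_tracks.tsv"))
    write.table(data.frame(member = names(ss_tracks), ss = unname(ss_tracks)),
                trk, sep = "\t", quote = FALSE, row.names = FALSE)
    files$ss_tracks_tsv <- trk
  }
  invisible(files)
}

#' Read a JSON report back
#' @param path path to a `*_report.json` file.
#' @return the parsed report list.
#' @export
read_report <- function(path) {
  if (!file.exists(path))
    cap_stop("capscan_io_error", "file not found: %s", path)
  rep <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(rep$schema, REPORT_SCHEMA))
    warning(sprintf("report schema '%s' differs from '%s'",
                    rep$schema, REPORT_SCHEMA))
  rep
}
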