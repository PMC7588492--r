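#' Write a synthetic cohort as plain-text files
#'
#' Emits the long event stream, static admission table, drug events and
#' surgery texts as CSV with ISO-8601 timestamps (hours are anchored at a
#' nominal admission datetime), the ground truth as a separate JSON file
#' (so the pipeline can be run blinded against the CSVs alone), and the
#' generating configuration as YAML.
#'
#' @param cohort an `aki_cohort`.
#' @param dir output directory.
#' @param origin nominal admission datetime anchoring hour 0.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, origin = "2020-01-01 00:00:00") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.POSIXct(origin, tz = "UTC")
  iso <- function(h) format(t0 + h * 3600, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  ev <- dplyr::mutate(cohort$events, timestamp = iso(.data$time_h))
  utils::write.csv(
    ev[, c("admission_id", "timestamp", "channel", "value", "location")],
    file.path(dir, "events.csv"), row.names = FALSE)
  st <- dplyr::mutate(cohort$static,
                      surgery_start = iso(.data$surgery_start_h),
                      surgery_end = iso(.data$surgery_end_h),
                      discharge = iso(.data$discharge_h))
  utils::write.csv(st, file.path(dir, "static.csv"), row.names = FALSE)
  dr <- dplyr::mutate(cohort$drugs, timestamp = iso(.data$time_h))
  utils::write.csv(dr[, c("admission_id", "timestamp", "agent")],
                   file.path(dir, "drugs.csv"), row.names = FALSE)
  utils::write.csv(cohort$surgery_text, file.path(dir, "surgery_text.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$locations, file.path(dir, "locations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA, na = "null")
  yaml::write_yaml(unclass(cohort$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the CSV/JSON/YAML files.
#' @param origin the anchor datetime used when writing.
#' @return an `aki_cohort` (without truth if `blinded = TRUE`).
#' @param blinded skip the ground-truth file.
#' @export
read_cohort <- function(dir, origin = "2020-01-01 00:00:00",
                        blinded = FALSE) {
  t0 <- as.POSIXct(origin, tz = "UTC")
  hrs <- function(ts) as.numeric(difftime(
    as.POSIXct(ts, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"), t0,
    units = "hours"))
  rd <- function(f) tibble::as_tibble(
    utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE))
  ev <- rd("events.csv")
  ev$time_h <- hrs(ev$timestamp)
  st <- rd("static.csv")
  dr <- rd("drugs.csv")
  dr$time_h <- hrs(dr$timestamp)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$criterion_mix <- unlist(cfg$criterion_mix)
  cfg <- structure(cfg, class = "aki_cohort_config")
  out <- list(
    config = cfg,
    static = st,
    events = ev[, c("admission_id", "time_h", "channel", "value", "location")],
    locations = rd("locations.csv"),
    drugs = dr[, c("admission_id", "time_h", "agent")],
    surgery_text = rd("surgery_text.csv"),
    truth = if (!blinded) tibble::as_tibble(
      jsonlite::read_json(file.path(dir, "truth.json"),
                          simplifyVector = TRUE)),
    channel_defaults = channel_defaults(cfg)
  )
  structure(out, class = "aki_cohort")
}

#' Write labels as JSON lines
#'
#' One JSON object per admission: id, label, onsets, criterion, baseline,
#' exclusion reason.
#'
#' @param labels label tibble from [label_cohort()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_labels_jsonl <- function(labels, path) {
  lines <- vapply(seq_len(nrow(labels)), function(i) {
    jsonlite::toJSON(as.list(labels[i, ]), auto_unbox = TRUE, digits = NA,
                     na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read one feature grid as CSV plus JSON sidecar
#'
#' The wide CSV has one row per grid timestamp; the sidecar records the
#' admission id, label, window, feature roster and the provenance mask,
#' so a grid round-trips exactly.
#'
#' @param grid an `aki_grid`.
#' @param stem file stem; writes `<stem>.csv` and `<stem>.json`.
#' @return `stem`, invisibly.
#' @export
write_feature_grid <- function(grid, stem) {
  utils::write.csv(grid$values, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(admission_id = grid$admission_id %||% NA,
         label = grid$label %||% NA,
         window = grid$window, scaled = grid$scaled, mask = grid$mask),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(stem)
}

#' @rdname write_feature_grid
#' @export
read_feature_grid <- function(stem) {
  vals <- tibble::as_tibble(utils::read.csv(paste0(stem, ".csv"),
                                            check.names = FALSE))
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  structure(list(values = vals, mask = tibble::as_tibble(meta$mask),
                 window = tibble::as_tibble(meta$window),
                 scaled = meta$scaled,
                 admission_id = meta$admission_id, label = meta$label),
            class = "aki_grid")
}
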