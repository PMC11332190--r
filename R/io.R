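# Plain-text interchange: CSV for detections/stations/trips/kills/traits,
# GPX 1.1 for tracks. Timestamps are ISO-8601 UTC throughout.

parse_time_cols <- function(df, cols) {
  for (cl in intersect(cols, names(df)))
    df[[cl]] <- as.POSIXct(df[[cl]], tz = "UTC",
                           tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                          "%Y-%m-%d"))
  df
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits `detections.csv`, `stations.csv`, `trips.csv`, `kills.csv`,
#' `traits.csv` and (when tracks exist) `tracks.gpx`.
#'
#' @param ct list from [simulate_camera_traps()].
#' @param hunts list from [simulate_hunts()].
#' @param traits species trait table.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ct, hunts, traits, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iso <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  w <- function(df, f) utils::write.csv(df, file.path(dir, f), row.names = FALSE)
  d <- ct$detections; d$timestamp <- iso(d$timestamp)
  w(d, "detections.csv")
  s <- ct$stations
  s$deploy_start <- iso(s$deploy_start); s$deploy_end <- iso(s$deploy_end)
  w(s, "stations.csv")
  tr <- hunts$trips; tr$depart <- iso(tr$depart); tr$return <- iso(tr$return)
  w(tr, "trips.csv")
  k <- hunts$kills; k$kill_time <- iso(k$kill_time)
  w(k, "kills.csv")
  w(traits, "traits.csv")
  if (!is.null(hunts$tracks)) write_gpx(hunts$tracks, file.path(dir, "tracks.gpx"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir directory containing the CSV/GPX files.
#' @return list with `detections`, `stations`, `trips`, `kills`, `traits`
#'   and `tracks` (`NULL` when absent).
#' @export
read_dataset <- function(dir) {
  r <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  tracks <- NULL
  if (file.exists(file.path(dir, "tracks.gpx"))) {
    tracks <- read_gpx(file.path(dir, "tracks.gpx"))
  }
  trips <- parse_time_cols(r("trips.csv"), c("depart", "return"))
  if (!is.null(tracks)) {
    tracks$hunter_id <- trips$hunter_id[match(tracks$trip_id, trips$trip_id)]
    tracks$community <- trips$community[match(tracks$trip_id, trips$trip_id)]
  }
  list(detections = parse_time_cols(r("detections.csv"), "timestamp"),
       stations = parse_time_cols(r("stations.csv"), c("deploy_start", "deploy_end")),
       trips = trips,
       kills = parse_time_cols(r("kills.csv"), "kill_time"),
       traits = r("traits.csv"),
       tracks = tracks)
}
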