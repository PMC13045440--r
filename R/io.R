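#' @title File formats for CLAMS-style data streams
#' @description
#' The package defines a documented, byte-stable CSV dialect standing in for
#' proprietary instrument exports: comma-delimited, UTF-8, header line,
#' ISO-8601 local-clock timestamps (`YYYY-MM-DDTHH:MM:SS`), fixed decimal
#' places (intake 2 dp, gas rates 4 dp). Durations are never stored; they
#' are derived as `end - start`. Four files make up a dataset:
#' `events.csv` (`animal_id,start,end,intake_g`), `calorimetry.csv`
#' (`animal_id,time,vo2_l_h,vco2_l_h`), `activity.csv`
#' (`animal_id,time,axis,beam_index`) and `manifest.yaml` (light schedule,
#' phase labels per day, diet energy density, protocol windows).
#' @name clams-io
NULL

ts_fmt <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
ts_parse <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")

write_lines_atomic <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write feeding events
#'
#' @param events Tibble with `animal_id`, `start`, `end`, `intake_g`.
#' @param path Output file path.
#' @return The path, invisibly. Two writes of the same data are
#'   byte-identical.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("animal_id", "start", "end", "intake_g") %in% names(events)))
  lines <- c("animal_id,start,end,intake_g",
             sprintf("%s,%s,%s,%.2f", events$animal_id,
                     ts_fmt(events$start), ts_fmt(events$end),
                     events$intake_g))
  write_lines_atomic(lines, path)
}

#' Read and validate feeding events
#'
#' @param path Path to an `events.csv` file.
#' @param manifest Optional manifest (list as produced by [read_manifest()]
#'   or a study's `$manifest`); when given, animal ids are checked against
#'   it.
#' @return A validated tibble sorted by (animal, start). Malformed rows,
#'   rows with `end < start`, negative intakes, overlapping events within an
#'   animal, or unknown animal ids raise errors naming the offending data
#'   row number.
#' @export
read_events <- function(path, manifest = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    animal_id = readr::col_character(),
    start = readr::col_character(),
    end = readr::col_character(),
    intake_g = readr::col_double())))
  if (!identical(names(df), c("animal_id", "start", "end", "intake_g")))
    stop("parse error: header does not match events.csv dialect", call. = FALSE)
  start <- ts_parse(df$start); end <- ts_parse(df$end)
  bad <- which(is.na(start) | is.na(end) | is.na(df$intake_g))
  if (length(bad))
    stop("parse error: malformed row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- which(end < start)
  if (length(bad))
    stop("validation error: end < start at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(df$intake_g < 0)
  if (length(bad))
    stop("validation error: negative intake at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(manifest)) {
    known <- manifest$animals %||% character()
    bad <- which(!df$animal_id %in% known)
    if (length(bad))
      stop("validation error: unknown animal id at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(animal_id = df$animal_id, start = start, end = end,
                        intake_g = df$intake_g)
  ord <- order(out$animal_id, out$start)
  out <- out[ord, ]
  # overlap check (per animal, in sorted order); report original row numbers
  orig <- seq_len(nrow(df))[ord]
  for (id in unique(out$animal_id)) {
    i <- which(out$animal_id == id)
    if (length(i) > 1) {
      ov <- which(utils::head(out$end[i], -1) > out$start[i][-1])
      if (length(ov))
        stop("validation error: overlapping events for animal ", id,
             " at row(s) ", paste(orig[i][ov + 1], collapse = ", "),
             call. = FALSE)
    }
  }
  out
}

#' Write/read calorimetry scans
#' @param samples Tibble with `animal_id`, `time`, `vo2_l_h`, `vco2_l_h`.
#' @param path File path.
#' @return `write_calorimetry()` the path invisibly; `read_calorimetry()` a
#'   validated tibble (positive gas rates enforced).
#' @export
write_calorimetry <- function(samples, path) {
  stopifnot(all(c("animal_id", "time", "vo2_l_h", "vco2_l_h") %in% names(samples)))
  lines <- c("animal_id,time,vo2_l_h,vco2_l_h",
             sprintf("%s,%s,%.4f,%.4f", samples$animal_id, ts_fmt(samples$time),
                     samples$vo2_l_h, samples$vco2_l_h))
  write_lines_atomic(lines, path)
}

#' @rdname write_calorimetry
#' @export
read_calorimetry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    animal_id = readr::col_character(), time = readr::col_character(),
    vo2_l_h = readr::col_double(), vco2_l_h = readr::col_double())))
  if (!identical(names(df), c("animal_id", "time", "vo2_l_h", "vco2_l_h")))
    stop("parse error: header does not match calorimetry.csv dialect", call. = FALSE)
  time <- ts_parse(df$time)
  bad <- which(is.na(time) | is.na(df$vo2_l_h) | is.na(df$vco2_l_h))
  if (length(bad))
    stop("parse error: malformed row(s) ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(df$vo2_l_h <= 0 | df$vco2_l_h <= 0)
  if (length(bad))
    stop("validation error: non-positive gas rate at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  tibble::tibble(animal_id = df$animal_id, time = time,
                 vo2_l_h = df$vo2_l_h, vco2_l_h = df$vco2_l_h)
}

#' Write/read beam-break activity streams
#' @param activity Tibble with `animal_id`, `time`, `axis`, `beam_index`.
#' @param path File path.
#' @return `write_activity()` the path invisibly; `read_activity()` a
#'   validated tibble. Activity timestamps carry 0.1-s resolution.
#' @export
write_activity <- function(activity, path) {
  stopifnot(all(c("animal_id", "time", "axis", "beam_index") %in% names(activity)))
  secs <- as.numeric(activity$time) - as.numeric(ms_origin())
  lines <- c("animal_id,time_s,axis,beam_index",
             sprintf("%s,%.1f,%s,%d", activity$animal_id, secs,
                     activity$axis, activity$beam_index))
  write_lines_atomic(lines, path)
}

#' @rdname write_activity
#' @export
read_activity <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    animal_id = readr::col_character(), time_s = readr::col_double(),
    axis = readr::col_character(), beam_index = readr::col_integer())))
  if (!identical(names(df), c("animal_id", "time_s", "axis", "beam_index")))
    stop("parse error: header does not match activity.csv dialect", call. = FALSE)
  bad <- which(!df$axis %in% c("X", "Z") | is.na(df$beam_index) | df$beam_index < 0)
  if (length(bad))
    stop("validation error: bad axis/beam at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  tibble::tibble(animal_id = df$animal_id,
                 time = ms_origin() + df$time_s,
                 axis = df$axis, beam_index = df$beam_index)
}

#' Write/read the study manifest
#'
#' The manifest records the cohort (animal ids), the light schedule, the
#' diet energy density, the master seed and the per-day phase/protocol
#' labels, as a YAML document.
#'
#' @param manifest A manifest list (e.g. `generate_study(cfg)$manifest`).
#' @param path File path.
#' @return `write_manifest()` the path invisibly; `read_manifest()` the
#'   manifest list with `phases` restored as a tibble.
#' @export
write_manifest <- function(manifest, path) {
  m <- manifest
  m$phases <- as.data.frame(m$phases)
  yaml::write_yaml(m, path, column.major = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- yaml::read_yaml(path)
  if (!is.null(m$phases)) m$phases <- dplyr::bind_rows(m$phases)
  if (!is.null(m$light_on) && !is.null(m$light_off)) {
    span <- (m$light_off - m$light_on) %% 24
    if (span <= 0 || span >= 24)
      stop("validation error: light schedule must span part of a 24-h day",
           call. = FALSE)
  }
  m
}
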