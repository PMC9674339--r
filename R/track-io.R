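#' Coerce and validate a track table
#'
#' A track table holds one or more objects' time series of positions: one row
#' per frame, columns `object_id`, `t` (minutes), `x`, `y` and optionally `z`
#' (micrometres). All downstream motility and geometry functions consume this
#' layout. `as_tracks()` checks the invariants every operation relies on:
#' time stamps strictly increasing within each object, no duplicated
#' `(object_id, t)` rows, and a single shared dimensionality (2D or 3D).
#'
#' @param df A data frame with columns `object_id`, `t`, `x`, `y` and
#'   optionally `z`.
#' @return A tibble sorted by `object_id` then `t`, with class `effero_tracks`.
#' @examples
#' as_tracks(data.frame(object_id = "a", t = 0:2, x = 0:2, y = 0, z = 0))
#' @export
as_tracks <- function(df) {
  df <- as_tibble(df)
  need <- c("object_id", "t", "x", "y")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("track table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) abort("track table is empty")
  df$object_id <- as.character(df$object_id)
  keep <- intersect(c("object_id", "t", "x", "y", "z"), names(df))
  extra <- setdiff(names(df), keep)
  df <- df[c(keep, extra)]
  # mixed dimensionality: z present for some rows of an object but not others,
  # or across objects
  if ("z" %in% names(df)) {
    has_z <- !is.na(df$z)
    if (any(has_z) && !all(has_z)) {
      bad <- unique(df$object_id[has_z != has_z[1]])
      abort(paste0("mixed dimensionality: z defined for only part of the table (e.g. object ",
                   bad[1], ")"))
    }
    if (!any(has_z)) df$z <- NULL
  }
  df <- dplyr::arrange(df, .data$object_id, .data$t)
  dup <- duplicated(df[c("object_id", "t")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf("duplicate (object_id, t) row: object %s at t = %g",
                  df$object_id[i], df$t[i]))
  }
  bad <- df %>%
    dplyr::group_by(.data$object_id) %>%
    dplyr::summarise(ok = all(diff(.data$t) > 0) || dplyr::n() == 1) %>%
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(paste0("non-monotonic time stamps for object ", bad$object_id[1]))
  }
  class(df) <- c("effero_tracks", class(df))
  df
}

#' Read a track table from CSV
#'
#' Reads per-object coordinate time series exported from common tracking
#' tools. Three column dialects are recognised:
#' \describe{
#'   \item{`generic`}{`object_id,t,x,y[,z]` -- the package's canonical layout.}
#'   \item{`mtrackj`}{`TID,t,x,y[,z]` as produced by point-tracking exports
#'     with a numeric track id.}
#'   \item{`imaris`}{`TrackID,Time,Position X,Position Y[,Position Z]` as in
#'     spot-detection exports.}
#' }
#' The exact schema of proprietary exports varies by version; the dialects are
#' best-effort emulations and any other layout can be renamed to `generic`.
#'
#' Internal units are fixed to micrometres and minutes. If the source file
#' uses other units, declare them via `time_unit`/`length_unit` or with a
#' JSON/YAML sidecar file (same path plus `.json`/`.yaml`) containing keys
#' `time_unit` (`"s"`, `"min"` or `"h"`) and `length_unit` (`"um"`, `"nm"` or
#' `"mm"`); values are converted at load.
#'
#' @param path CSV file path.
#' @param dialect Column dialect, see Details.
#' @param time_unit,length_unit Source units, overriding any sidecar.
#' @return A validated `effero_tracks` tibble (see [as_tracks()]).
#' @export
read_tracks <- function(path, dialect = c("generic", "mtrackj", "imaris"),
                        time_unit = NULL, length_unit = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- as_tibble(utils::read.csv(path, check.names = FALSE))
  map <- switch(dialect,
    generic = c(object_id = "object_id", t = "t", x = "x", y = "y", z = "z"),
    mtrackj = c(object_id = "TID", t = "t", x = "x", y = "y", z = "z"),
    imaris  = c(object_id = "TrackID", t = "Time",
                x = "Position X", y = "Position Y", z = "Position Z")
  )
  present <- map[map %in% names(df)]
  missing <- setdiff(c("object_id", "t", "x", "y"), names(present))
  if (length(missing) > 0) {
    abort(sprintf("cannot resolve column(s) %s under dialect '%s'",
                  paste(missing, collapse = ", "), dialect))
  }
  out <- df[unname(present)]
  names(out) <- names(present)
  side <- read_units_sidecar(path)
  tu <- time_unit %||% side$time_unit %||% "min"
  lu <- length_unit %||% side$length_unit %||% "um"
  out$t <- out$t * time_factor(tu)
  for (cc in intersect(c("x", "y", "z"), names(out))) {
    out[[cc]] <- out[[cc]] * length_factor(lu)
  }
  as_tracks(out)
}

read_units_sidecar <- function(path) {
  for (ext in c(".json", ".yaml", ".yml")) {
    sp <- paste0(path, ext)
    if (file.exists(sp)) {
      if (ext == ".json") return(jsonlite::read_json(sp, simplifyVector = TRUE))
      return(yaml::read_yaml(sp))
    }
  }
  list()
}

time_factor <- function(unit) {
  switch(unit, s = 1 / 60, sec = 1 / 60, min = 1, h = 60, hr = 60,
         abort(paste0("unknown time unit: ", unit)))
}

length_factor <- function(unit) {
  switch(unit, um = 1, micron = 1, nm = 1e-3, mm = 1e3,
         abort(paste0("unknown length unit: ", unit)))
}

#' Write a track table to canonical CSV
#'
#' Writes the canonical layout `object_id,t,x,y[,z]`, rows ordered by object
#' then time, full floating-point precision, so that
#' `read_tracks(write_tracks(x))` round-trips every value exactly.
#'
#' @param tracks A track table (coerced via [as_tracks()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  tracks <- as_tracks(tracks)
  cols <- intersect(c("object_id", "t", "x", "y", "z"), names(tracks))
  write_exact_csv(tracks[cols], path)
  invisible(path)
}

# CSV writer with bit-exact doubles: %.17g is unambiguous and read.csv's
# strtod parse is correctly rounded, so write -> read -> write is stable
write_exact_csv <- function(df, path) {
  out <- df
  for (cc in names(out)) {
    if (is.double(out[[cc]])) out[[cc]] <- sprintf("%.17g", out[[cc]])
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort(paste0("cannot write to path: ", path))
  invisible(path)
}

#' Read or write an engulfment-event table
#'
#' Event tables record phagocytic attempts, one row per attempt, with columns
#' `cell_id`, `t_onset` (minutes), `x,y[,z]` (the phagosome position p, in
#' micrometres), `outcome` (`successful` or `aborted`) and `mode` (`BM` for
#' branch-mediated, `NBM` for non-branch-mediated, or `unknown`). Aborted
#' attempts are conventionally time-stamped at the cup 30 s after initial
#' contact.
#'
#' @param path CSV file path.
#' @param events For `write_events()`, an event table.
#' @return A tibble of events with an `event_id` column added if absent.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  as_events(as_tibble(utils::read.csv(path, check.names = FALSE)))
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  events <- as_events(events)
  write_exact_csv(events, path)
  invisible(path)
}

#' @rdname read_events
#' @export
as_events <- function(events) {
  events <- as_tibble(events)
  need <- c("cell_id", "t_onset", "x", "y", "outcome")
  missing <- setdiff(need, names(events))
  if (length(missing) > 0) {
    abort(paste0("event table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  events$cell_id <- as.character(events$cell_id)
  if (!"mode" %in% names(events)) events$mode <- "unknown"
  events$mode[is.na(events$mode)] <- "unknown"
  bad <- setdiff(unique(events$outcome), c("successful", "aborted"))
  if (length(bad) > 0) abort(paste0("unknown outcome value: ", bad[1]))
  bad <- setdiff(unique(events$mode), c("BM", "NBM", "unknown"))
  if (length(bad) > 0) abort(paste0("unknown mode value: ", bad[1]))
  if (!"event_id" %in% names(events)) {
    events$event_id <- sprintf("ev%03d", seq_len(nrow(events)))
  }
  events$event_id <- as.character(events$event_id)
  events
}
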