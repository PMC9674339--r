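#' Assemble an efferocytosis dataset
#'
#' Bundles the tables an imaging session produces into one object:
#' \describe{
#'   \item{tracks}{tibble `cell_id, role, track_id, t, x, y[, z]`. `role` is
#'     one of `centre` (cell-centre track, cc), `centrosome` (cs), `phagosome`
#'     (p, one track per event, `track_id` = the event id) or `tip` (branch
#'     tip).}
#'   \item{events}{event table as in [read_events()].}
#'   \item{shapes}{optional per-frame shape measurements
#'     `cell_id, t, V, A` (volume in um^3, surface area in um^2).}
#'   \item{cells}{optional per-cell table `cell_id, radius` (um).}
#'   \item{points}{optional labelled point sets, `label, x, y[, z]`, e.g.
#'     microglia and dead-neuron positions.}
#'   \item{metadata}{list; `dt` (frame interval, minutes) is used as the
#'     default grid spacing in event-window averaging.}
#' }
#' Units are micrometres and minutes throughout.
#'
#' @param tracks,events,shapes,cells,points,metadata See Details.
#' @return An object of class `effero_dataset`.
#' @export
effero_dataset <- function(tracks, events, shapes = NULL, cells = NULL,
                           points = NULL, metadata = list()) {
  tracks <- as_tibble(tracks)
  need <- c("cell_id", "role", "track_id", "t", "x", "y")
  missing <- setdiff(need, names(tracks))
  if (length(missing) > 0) {
    abort(paste0("dataset tracks lack column(s): ", paste(missing, collapse = ", ")))
  }
  tracks$cell_id <- as.character(tracks$cell_id)
  tracks$track_id <- as.character(tracks$track_id)
  tracks <- dplyr::arrange(tracks, .data$cell_id, .data$role, .data$track_id, .data$t)
  events <- as_events(events)
  structure(
    list(tracks = tracks, events = events,
         shapes = if (!is.null(shapes)) as_tibble(shapes),
         cells = if (!is.null(cells)) as_tibble(cells),
         points = if (!is.null(points)) as_tibble(points),
         metadata = metadata),
    class = "effero_dataset"
  )
}

#' @export
print.effero_dataset <- function(x, ...) {
  n_cells <- length(unique(x$tracks$cell_id))
  cat("<effero_dataset> ", n_cells, " cells, ",
      nrow(x$events), " events, ",
      nrow(x$tracks), " track rows\n", sep = "")
  if (!is.null(x$shapes)) cat("  shapes: ", nrow(x$shapes), " frames\n", sep = "")
  if (!is.null(x$points)) cat("  points: ", nrow(x$points), " (",
                              paste(unique(x$points$label), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# tracks of one role for one cell
cell_track <- function(dataset, cell_id, role, track_id = NULL) {
  tr <- dataset$tracks
  sel <- tr$cell_id == cell_id & tr$role == role
  if (!is.null(track_id)) sel <- sel & tr$track_id == track_id
  tr[sel, , drop = FALSE]
}

#' Validate a dataset against its invariants
#'
#' Reports (rather than throws) every violation found: events whose `cell_id`
#' has no centre track, events timed outside their cell's observation window,
#' non-positive volume or surface area in the shape table, non-monotonic track
#' time stamps, and outcome/mode values outside the closed vocabularies. An
#' empty result means the dataset satisfies all invariants.
#'
#' @param dataset An [effero_dataset()].
#' @return A tibble with columns `table`, `id`, `problem`; zero rows if clean.
#' @export
validate_dataset <- function(dataset) {
  v <- list()
  add <- function(table, id, problem) {
    v[[length(v) + 1]] <<- tibble(table = table, id = as.character(id), problem = problem)
  }
  tr <- dataset$tracks
  ev <- dataset$events

  centre_cells <- unique(tr$cell_id[tr$role == "centre"])
  for (i in seq_len(nrow(ev))) {
    cid <- ev$cell_id[i]
    if (!cid %in% centre_cells) {
      add("events", ev$event_id[i], paste0("cell_id '", cid, "' has no centre track"))
      next
    }
    cc <- tr[tr$cell_id == cid & tr$role == "centre", ]
    if (ev$t_onset[i] < min(cc$t) || ev$t_onset[i] > max(cc$t)) {
      add("events", ev$event_id[i],
          sprintf("t_onset %g outside observation window [%g, %g]",
                  ev$t_onset[i], min(cc$t), max(cc$t)))
    }
  }
  if (!all(ev$outcome %in% c("successful", "aborted"))) {
    add("events", "*", "outcome outside {successful, aborted}")
  }
  if (!all(ev$mode %in% c("BM", "NBM", "unknown"))) {
    add("events", "*", "mode outside {BM, NBM, unknown}")
  }
  bad_t <- tr %>%
    dplyr::group_by(.data$cell_id, .data$role, .data$track_id) %>%
    dplyr::summarise(ok = all(diff(.data$t) > 0) || dplyr::n() == 1, .groups = "drop") %>%
    dplyr::filter(!.data$ok)
  for (i in seq_len(nrow(bad_t))) {
    add("tracks", paste(bad_t$cell_id[i], bad_t$role[i], bad_t$track_id[i]),
        "non-monotonic time stamps")
  }
  if (!is.null(dataset$shapes)) {
    sh <- dataset$shapes
    bad <- which(sh$V <= 0 | sh$A <= 0)
    for (i in bad) {
      add("shapes", sh$cell_id[i],
          sprintf("non-positive V or A at t = %g (V = %g, A = %g)",
                  sh$t[i], sh$V[i], sh$A[i]))
    }
  }
  if (length(v) == 0) {
    return(tibble(table = character(), id = character(), problem = character()))
  }
  dplyr::bind_rows(v)
}
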