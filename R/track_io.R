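#' @importFrom rlang .data abort warn .env
#' @importFrom dplyr %>%
NULL

# Required columns of the track CSV dialect (micrometres and seconds only).
.track_required_cols <- c("axon_id", "track_id", "frame", "t_s", "x_um", "y_um",
                          "organelle")
.track_optional_cols <- c("animal_id", "intensity", "length_um",
                          "video_duration_s")
.organelle_levels <- c("endosome", "mitochondrion")

#' Read a track table
#'
#' Reads time-lapse particle tracks from the package's plain CSV dialect:
#' one row per spot, comma-separated, UTF-8, header required, positions in
#' micrometres, time in seconds. Required columns are `axon_id`, `track_id`,
#' `frame`, `t_s`, `x_um`, `y_um` and `organelle`; `animal_id`, `intensity`,
#' `length_um` (organelle length, mitochondria) and `video_duration_s` are
#' optional and carried through when present.
#'
#' @param path Path to a CSV file.
#' @return A tibble of spots, sorted by `axon_id`, `track_id`, `frame`, with
#'   one row per spot.
#' @details A track is identified by the pair (`axon_id`, `track_id`).
#'   Duplicate (`axon_id`, `track_id`, `frame`) rows and non-increasing time
#'   within a track are rejected; every track must have at least two spots
#'   and finite positions.
#' @seealso [write_tracks_csv()], [read_trackmate_xml()]
#' @export
read_tracks_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("track file not found: ", path), class = "nodetrans_io_error")
  }
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(.track_required_cols, names(dat))
  if (length(missing) > 0) {
    abort(paste0("track table is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "nodetrans_format_error")
  }
  dat <- tibble::as_tibble(dat)
  dat$track_id <- as.character(dat$track_id)
  dat$axon_id <- as.character(dat$axon_id)
  if (!"animal_id" %in% names(dat)) dat$animal_id <- "animal1"
  dat$animal_id <- as.character(dat$animal_id)
  validate_tracks(dat)
}

#' Validate a spot table
#'
#' Checks the track-table invariants: finite positions, strictly increasing
#' frames and times within each track, no duplicated frames, at least two
#' spots per track, and a known organelle class.
#'
#' @param tracks A spot tibble as returned by [read_tracks_csv()].
#' @return The input, sorted by axon, track and frame (invisibly usable in a
#'   pipe).
#' @export
validate_tracks <- function(tracks) {
  tracks <- dplyr::arrange(tracks, .data$axon_id, .data$track_id, .data$frame)
  if (nrow(tracks) == 0) return(tracks)
  if (!all(is.finite(tracks$x_um)) || !all(is.finite(tracks$y_um))) {
    abort("spot positions must be finite", class = "nodetrans_validation_error")
  }
  bad_class <- setdiff(unique(tracks$organelle), .organelle_levels)
  if (length(bad_class) > 0) {
    abort(paste0("unknown organelle class: ", paste(bad_class, collapse = ", ")),
          class = "nodetrans_validation_error")
  }
  chk <- tracks %>%
    dplyr::group_by(.data$axon_id, .data$track_id) %>%
    dplyr::summarise(
      n = dplyr::n(),
      dup = anyDuplicated(.data$frame) > 0,
      mono_f = all(diff(.data$frame) > 0),
      mono_t = if (dplyr::n() > 1) all(diff(.data$t_s) > 0) else TRUE,
      .groups = "drop"
    )
  if (any(chk$dup)) {
    abort(paste0("duplicated (track_id, frame) rows in track(s): ",
                 paste(chk$track_id[chk$dup], collapse = ", ")),
          class = "nodetrans_validation_error")
  }
  if (any(!chk$mono_f) || any(!chk$mono_t)) {
    bad <- chk$track_id[!chk$mono_f | !chk$mono_t]
    abort(paste0("non-monotone frame/time within track(s): ",
                 paste(bad, collapse = ", ")),
          class = "nodetrans_validation_error")
  }
  if (any(chk$n < 2)) {
    abort(paste0("track(s) with fewer than 2 spots: ",
                 paste(chk$track_id[chk$n < 2], collapse = ", ")),
          class = "nodetrans_validation_error")
  }
  if ("video_duration_s" %in% names(tracks)) {
    span <- tracks %>%
      dplyr::group_by(.data$axon_id, .data$track_id) %>%
      dplyr::summarise(ok = max(.data$t_s) - min(.data$t_s) <=
                         .data$video_duration_s[1] + 1e-9, .groups = "drop")
    if (any(!span$ok)) {
      abort("track time span exceeds video_duration_s",
            class = "nodetrans_validation_error")
    }
  }
  tracks
}

#' Write a track table
#'
#' Writes spots in the package CSV dialect with a deterministic column order
#' so that [read_tracks_csv()] round-trips the dataset field-for-field.
#'
#' @param tracks A spot tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  if (nrow(tracks) > 0) {
    if (!all(is.finite(tracks$x_um)) || !all(is.finite(tracks$y_um))) {
      abort("refusing to write non-finite spot positions",
            class = "nodetrans_validation_error")
    }
    tracks <- validate_tracks(tracks)
  }
  cols <- c(.track_required_cols,
            intersect(.track_optional_cols, names(tracks)))
  out <- tracks[intersect(cols, names(tracks))]
  ok <- tryCatch({
    readr::write_csv(out, path, progress = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(paste0("cannot write track table to ", path, ": ",
                 conditionMessage(ok)), class = "nodetrans_io_error")
  }
  invisible(path)
}

#' Read a TrackMate-style XML export
#'
#' Ingests the minimal subset of a TrackMate XML model needed for transport
#' analysis: spots (`POSITION_X`, `POSITION_Y`, `POSITION_T`, `FRAME`) and
#' track membership from the edges of each `Track` element. All other
#' attributes are ignored. Positions are converted to micrometres using the
#' model's `spatialunits` attribute.
#'
#' @param path Path to the XML file.
#' @param organelle Organelle class to assign (`"endosome"` or
#'   `"mitochondrion"`); TrackMate files carry no class.
#' @param axon_id,animal_id Identifiers to attach to the dataset.
#' @return A spot tibble in the same structure as [read_tracks_csv()].
#' @details Spots referenced by no track (orphans) are dropped with a
#'   warning stating the count; edges referencing unknown spot IDs raise an
#'   error listing the IDs. Known spatial units: `micron`, `um`, `µm`
#'   (factor 1) and `mm` (factor 1000).
#' @export
read_trackmate_xml <- function(path, organelle = "endosome",
                               axon_id = "axon1", animal_id = "animal1") {
  doc <- xml2::read_xml(path)
  model <- xml2::xml_find_first(doc, ".//Model")
  if (inherits(model, "xml_missing")) {
    abort("no <Model> element found", class = "nodetrans_format_error")
  }
  units <- xml2::xml_attr(model, "spatialunits")
  if (is.na(units)) units <- ""
  factor <- switch(tolower(units),
                   "micron" = 1, "um" = 1, "µm" = 1, "mm" = 1000,
                   NULL)
  if (is.null(factor)) {
    abort(paste0("unknown spatial units: ", if (nzchar(units)) units else "<missing>"),
          class = "nodetrans_format_error")
  }
  spot_nodes <- xml2::xml_find_all(doc, ".//AllSpots//Spot")
  spots <- tibble::tibble(
    spot_id = xml2::xml_attr(spot_nodes, "ID"),
    frame = as.integer(xml2::xml_attr(spot_nodes, "FRAME")),
    t_s = as.numeric(xml2::xml_attr(spot_nodes, "POSITION_T")),
    x_um = as.numeric(xml2::xml_attr(spot_nodes, "POSITION_X")) * factor,
    y_um = as.numeric(xml2::xml_attr(spot_nodes, "POSITION_Y")) * factor
  )
  track_nodes <- xml2::xml_find_all(doc, ".//AllTracks/Track")
  membership <- purrr::map_dfr(track_nodes, function(trk) {
    tid <- xml2::xml_attr(trk, "TRACK_ID")
    edges <- xml2::xml_find_all(trk, "./Edge")
    tibble::tibble(
      track_id = tid,
      spot_id = c(xml2::xml_attr(edges, "SPOT_SOURCE_ID"),
                  xml2::xml_attr(edges, "SPOT_TARGET_ID"))
    )
  })
  membership <- dplyr::distinct(membership)
  dangling <- setdiff(membership$spot_id, spots$spot_id)
  if (length(dangling) > 0) {
    abort(paste0("edges reference unknown spot ID(s): ",
                 paste(dangling, collapse = ", ")),
          class = "nodetrans_format_error")
  }
  n_orphans <- sum(!spots$spot_id %in% membership$spot_id)
  if (n_orphans > 0) {
    warn(paste0("dropped ", n_orphans, " spot(s) referenced by no track"))
  }
  out <- dplyr::inner_join(membership, spots, by = "spot_id") %>%
    dplyr::transmute(
      axon_id = .env$axon_id,
      track_id = .data$track_id,
      frame = .data$frame,
      t_s = .data$t_s,
      x_um = .data$x_um,
      y_um = .data$y_um,
      organelle = .env$organelle,
      animal_id = .env$animal_id
    ) %>%
    dplyr::arrange(.data$axon_id, .data$track_id, .data$frame)
  validate_tracks(out)
}

#' Define axon geometry
#'
#' The axon is represented by an ordered centerline polyline (vertices in
#' micrometres), the arclength of the node-of-Ranvier center along it, and
#' the sign convention mapping increasing arclength to the distal direction
#' (away from the soma, toward the muscle).
#'
#' @param centerline Two-column numeric matrix (or coercible) of polyline
#'   vertices, at least two rows.
#' @param node_center_arclength Arclength (micrometres) of the node center,
#'   in `[0, total length]`.
#' @param distal_sign `+1` if increasing arclength points distally, `-1`
#'   otherwise.
#' @return An `axon_geometry` object.
#' @export
axon_geometry <- function(centerline, node_center_arclength, distal_sign = 1) {
  centerline <- as.matrix(centerline)
  if (ncol(centerline) != 2 || nrow(centerline) < 2 ||
      !all(is.finite(centerline))) {
    abort("centerline must be a finite two-column matrix with >= 2 vertices",
          class = "nodetrans_validation_error")
  }
  seg <- diff(centerline)
  seg_len <- sqrt(rowSums(seg^2))
  if (sum(seg_len) <= 0) {
    abort("centerline has zero total length",
          class = "nodetrans_validation_error")
  }
  total <- sum(seg_len)
  if (node_center_arclength < 0 || node_center_arclength > total) {
    abort("node_center_arclength outside [0, total centerline length]",
          class = "nodetrans_validation_error")
  }
  if (!distal_sign %in% c(-1, 1)) {
    abort("distal_sign must be +1 or -1", class = "nodetrans_validation_error")
  }
  structure(
    list(centerline = centerline,
         node_center_arclength = node_center_arclength,
         distal_sign = distal_sign,
         cum_arclength = c(0, cumsum(seg_len)),
         total_length = total),
    class = "axon_geometry"
  )
}

#' @export
print.axon_geometry <- function(x, ...) {
  cat("<axon_geometry> ", nrow(x$centerline), " vertices, length ",
      round(x$total_length, 2), " um, node at ",
      round(x$node_center_arclength, 2), " um, distal sign ",
      x$distal_sign, "\n", sep = "")
  invisible(x)
}

#' Write/read axon geometry as JSON
#'
#' @param geometry An [axon_geometry()] object.
#' @param path File path.
#' @return `write_axon_geometry()` returns `path` invisibly;
#'   `read_axon_geometry()` returns an `axon_geometry`.
#' @export
write_axon_geometry <- function(geometry, path) {
  jsonlite::write_json(
    list(centerline = unname(geometry$centerline),
         node_center_arclength = geometry$node_center_arclength,
         distal_sign = geometry$distal_sign),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_axon_geometry
#' @export
read_axon_geometry <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  axon_geometry(g$centerline, g$node_center_arclength, g$distal_sign)
}

#' Project spots onto the axon centerline
#'
#' Assigns each spot a signed axial coordinate `s_um`: the arclength of the
#' nearest centerline point minus the node-center arclength, multiplied by
#' the distal sign, so that positive `s_um` is distal (toward the muscle)
#' and negative proximal (toward the soma). The perpendicular distance to
#' the nearest point is returned as `lateral_um`.
#'
#' @param tracks A spot tibble (see [read_tracks_csv()]).
#' @param geometry An [axon_geometry()] object.
#' @param max_lateral_um Spots farther than this from the centerline are
#'   excluded with a warning (default 10).
#' @return The spot tibble with `s_um` and `lateral_um` columns appended;
#'   excluded spots are dropped.
#' @details The nearest point is searched over all polyline segments with
#'   the spot projected (and clamped) onto each; exact ties between
#'   equidistant segments are broken toward the lower arclength, which makes
#'   the projection deterministic. Flipping `distal_sign` negates `s_um`
#'   exactly.
#' @export
project_to_axis <- function(tracks, geometry, max_lateral_um = 10) {
  stopifnot(inherits(geometry, "axon_geometry"))
  if (nrow(tracks) == 0) {
    tracks$s_um <- numeric(0)
    tracks$lateral_um <- numeric(0)
    return(tracks)
  }
  pr <- .project_points(cbind(tracks$x_um, tracks$y_um), geometry)
  tracks$s_um <- geometry$distal_sign *
    (pr$arclength - geometry$node_center_arclength)
  tracks$lateral_um <- pr$lateral
  far <- tracks$lateral_um > max_lateral_um
  if (any(far)) {
    warn(paste0("excluded ", sum(far), " spot(s) farther than ",
                max_lateral_um, " um from the centerline"))
    tracks <- tracks[!far, , drop = FALSE]
  }
  tracks
}

# Vectorized nearest-point projection of an n x 2 matrix onto the polyline.
# Returns arclength along the polyline and perpendicular (lateral) distance.
# Ties broken toward lower arclength by strict improvement while scanning
# segments in order.
.project_points <- function(pts, geometry) {
  v <- geometry$centerline
  cum <- geometry$cum_arclength
  n <- nrow(pts)
  best_d2 <- rep(Inf, n)
  best_arc <- rep(NA_real_, n)
  for (j in seq_len(nrow(v) - 1)) {
    a <- v[j, ]
    b <- v[j + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    px <- a[1] + t * ab[1]
    py <- a[2] + t * ab[2]
    d2 <- (pts[, 1] - px)^2 + (pts[, 2] - py)^2
    better <- d2 < best_d2 - 1e-12
    best_d2[better] <- d2[better]
    best_arc[better] <- cum[j] + t[better] * sqrt(len2)
  }
  list(arclength = best_arc, lateral = sqrt(best_d2))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
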