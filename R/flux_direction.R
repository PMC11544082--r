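#' Classify track motility and direction
#'
#' Labels each track `anterograde`, `retrograde` or `stationary`. A track is
#' stationary when it has no qualifying moving run (at least
#' `min_consecutive_moving_frames` consecutive non-pause steps) or when its
#' absolute net axial displacement over non-pause steps is below
#' `stationary_net_threshold` (one bin width by default). Otherwise the
#' label follows the sign of the summed axial displacement of non-pause
#' steps, positive being anterograde (distal-ward). An exact zero falls
#' back to the majority sign of moving steps; a remaining tie is called
#' stationary with a warning.
#'
#' @param steps A trimmed step tibble ([trim_terminal_pauses()]).
#' @param config An [analysis_config()].
#' @return One row per track: keys, `organelle` (if present), `label`,
#'   `net_axial_um`, `max_moving_run`.
#' @export
classify_motility <- function(steps, config = analysis_config()) {
  carry <- intersect(c("organelle", "length_um", "video_duration_s"),
                     names(steps))
  res <- steps %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c(.step_keys, carry)))) %>%
    dplyr::arrange(.data$frame_from, .by_group = TRUE) %>%
    dplyr::summarise(
      max_moving_run = .max_run(!.data$is_pause),
      net_axial_um = sum(.data$axial_delta_um[!.data$is_pause]),
      n_pos = sum(!.data$is_pause & .data$axial_delta_um > 0),
      n_neg = sum(!.data$is_pause & .data$axial_delta_um < 0),
      .groups = "drop"
    )
  qualifying <- res$max_moving_run >= config$min_consecutive_moving_frames
  lab <- ifelse(!qualifying |
                  abs(res$net_axial_um) < config$stationary_net_threshold,
                "stationary",
                ifelse(res$net_axial_um > 0, "anterograde",
                       ifelse(res$net_axial_um < 0, "retrograde", NA)))
  zero <- which(is.na(lab))
  if (length(zero) > 0) {
    maj <- sign(res$n_pos[zero] - res$n_neg[zero])
    lab[zero] <- c("stationary", "stationary", "anterograde")[maj + 2]
    lab[zero][maj == 0] <- "stationary"
    lab[zero][maj < 0] <- "retrograde"
    if (any(maj == 0)) {
      rlang::warn("tied zero net displacement: track(s) labelled stationary")
    }
  }
  res$label <- factor(lab, levels = c("anterograde", "retrograde", "stationary"))
  dplyr::select(res, -"n_pos", -"n_neg")
}

#' Count moving organelles per subdomain and direction
#'
#' For each subdomain and direction, counts the number of distinct
#' organelles (not steps) having at least one non-pause step in that
#' subdomain; an organelle contributes at most one to each cell regardless
#' of revisits. Only tracks labelled anterograde or retrograde count.
#'
#' @param steps A binned step tibble ([assign_bins()]).
#' @param labels Motility labels from [classify_motility()].
#' @return A tibble per (animal, axon, subdomain, direction) with
#'   `n_organelles` and, when available, `video_duration_s`; cells with no
#'   organelles are present with zero counts.
#' @export
count_directional_movements <- function(steps, labels) {
  motile <- dplyr::filter(labels, .data$label != "stationary")
  dur <- if ("video_duration_s" %in% names(steps)) {
    steps %>%
      dplyr::distinct(.data$animal_id, .data$axon_id, .data$video_duration_s)
  } else NULL
  counts <- steps %>%
    dplyr::inner_join(dplyr::select(motile, dplyr::all_of(.step_keys), "label"),
                      by = .step_keys) %>%
    dplyr::filter(!.data$is_pause, .data$subdomain != "outside") %>%
    dplyr::distinct(.data$animal_id, .data$axon_id, .data$track_id,
                    .data$subdomain, .data$label) %>%
    dplyr::count(.data$animal_id, .data$axon_id, .data$subdomain, .data$label,
                 name = "n_organelles") %>%
    tidyr::complete(
      tidyr::nesting(!!rlang::sym("animal_id"), !!rlang::sym("axon_id")),
      subdomain = factor(c("proximal", "center", "distal"),
                         levels = levels(steps$subdomain)),
      label = factor(c("anterograde", "retrograde"),
                     levels = levels(labels$label)),
      fill = list(n_organelles = 0L)
    ) %>%
    dplyr::rename(direction = "label")
  if (!is.null(dur)) {
    counts <- dplyr::left_join(counts, dur, by = c("animal_id", "axon_id"))
  }
  counts
}

#' Convert directional counts to per-minute flux
#'
#' Normalizes organelle counts to the duration of each video:
#' `flux = count * 60 / video_duration_s`.
#'
#' @param counts Output of [count_directional_movements()]; must carry
#'   `video_duration_s` (or supply `video_duration_s`).
#' @param video_duration_s Optional scalar duration (seconds) overriding the
#'   column.
#' @return `counts` with a `flux_per_min` column.
#' @export
flux_per_minute <- function(counts, video_duration_s = NULL) {
  if (!is.null(video_duration_s)) counts$video_duration_s <- video_duration_s
  if (!"video_duration_s" %in% names(counts)) {
    rlang::abort("video_duration_s required to compute flux",
                 class = "nodetrans_validation_error")
  }
  if (any(counts$video_duration_s <= 0)) {
    rlang::abort("video duration must be positive",
                 class = "nodetrans_validation_error")
  }
  counts$flux_per_min <- counts$n_organelles * 60 / counts$video_duration_s
  counts
}

#' Pool flux across subdomains
#'
#' Per direction: within each axon, the mean of the subdomain fluxes; then
#' the mean across axons.
#'
#' @param flux Output of [flux_per_minute()].
#' @return One row per direction with `flux_per_min`.
#' @export
pool_flux <- function(flux) {
  flux %>%
    dplyr::group_by(.data$animal_id, .data$axon_id, .data$direction) %>%
    dplyr::summarise(flux_per_min = mean(.data$flux_per_min), .groups = "drop") %>%
    dplyr::group_by(.data$direction) %>%
    dplyr::summarise(flux_per_min = mean(.data$flux_per_min), .groups = "drop")
}

#' Direction fractions of motile organelles
#'
#' @param labels Motility labels from [classify_motility()].
#' @return A tibble with the anterograde and retrograde fractions of motile
#'   tracks (summing to 1). All-stationary input is an error.
#' @export
direction_fraction <- function(labels) {
  motile <- dplyr::filter(labels, .data$label != "stationary")
  if (nrow(motile) == 0) {
    rlang::abort("direction fractions undefined: no motile tracks",
                 class = "nodetrans_validation_error")
  }
  motile %>%
    dplyr::count(direction = factor(as.character(.data$label),
                                    levels = c("anterograde", "retrograde"))) %>%
    tidyr::complete(direction = factor(c("anterograde", "retrograde"),
                                       levels = c("anterograde", "retrograde")),
                    fill = list(n = 0L)) %>%
    dplyr::mutate(fraction = .data$n / sum(.data$n))
}

#' Mitochondrial length by motility class and region
#'
#' Mean organelle length per motility class (stationary / anterograde /
#' retrograde) and axonal region. A track's region is the modal subdomain
#' of its steps; tracks whose modal subdomain is the nodal center are
#' grouped with the distal region, and only proximal and distal regions are
#' reported.
#'
#' @param steps A binned step tibble carrying `length_um`.
#' @param labels Motility labels from [classify_motility()].
#' @return A tibble per (label, region): `mean_length_um`, `n`. Classes
#'   without length data are dropped with a warning.
#' @export
length_summary <- function(steps, labels) {
  if (!"length_um" %in% names(steps)) {
    rlang::abort("length_um column required", class = "nodetrans_validation_error")
  }
  region <- steps %>%
    dplyr::filter(.data$subdomain != "outside") %>%
    dplyr::count(.data$animal_id, .data$axon_id, .data$track_id,
                 .data$subdomain) %>%
    dplyr::group_by(.data$animal_id, .data$axon_id, .data$track_id) %>%
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(region = dplyr::if_else(.data$subdomain == "proximal",
                                          "proximal", "distal")) %>%
    dplyr::select(dplyr::all_of(.step_keys), "region")
  lens <- steps %>%
    dplyr::distinct(.data$animal_id, .data$axon_id, .data$track_id,
                    .data$length_um) %>%
    dplyr::inner_join(region, by = .step_keys) %>%
    dplyr::inner_join(dplyr::select(labels, dplyr::all_of(.step_keys), "label"),
                      by = .step_keys)
  missing <- lens %>%
    dplyr::filter(is.na(.data$length_um)) %>%
    dplyr::distinct(.data$label)
  if (nrow(missing) > 0) {
    rlang::warn(paste0("missing lengths; excluded from class(es): ",
                       paste(missing$label, collapse = ", ")))
  }
  lens %>%
    dplyr::filter(!is.na(.data$length_um)) %>%
    dplyr::group_by(.data$label, .data$region) %>%
    dplyr::summarise(mean_length_um = mean(.data$length_um),
                     n = dplyr::n(), .groups = "drop")
}
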