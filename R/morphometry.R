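.measure_types <- c("internode_diameter", "node_diameter", "node_length")

#' Summarize manual nodal morphometry measurements
#'
#' Aggregates a long table of manual measurements (orthogonal diameters of
#' the internode and nodal constriction, nodal constriction lengths) into
#' per-axon means, per-animal means of axon means, and the
#' internode-to-node diameter ratio (computed per axon, then averaged).
#' Warns when an animal contributes fewer than 10 measurements or fewer
#' than 3 axons.
#'
#' @param table Tibble with columns `animal_id`, `axon_id`, `measure_type`
#'   (one of `internode_diameter`, `node_diameter`, `node_length`) and
#'   `value_um` (> 0).
#' @return A list with tibbles `per_axon` (wide, one row per axon, plus
#'   `diameter_ratio`), `per_animal` (means of axon means) and `checks`
#'   (per-animal measurement/axon counts with status).
#' @export
summarize_measurements <- function(table) {
  bad_type <- setdiff(unique(table$measure_type), .measure_types)
  if (length(bad_type) > 0) {
    rlang::abort(paste0("unknown measure_type: ",
                        paste(bad_type, collapse = ", ")),
                 class = "nodetrans_validation_error")
  }
  if (any(!is.finite(table$value_um) | table$value_um <= 0)) {
    rlang::abort("value_um must be positive", class = "nodetrans_validation_error")
  }
  per_axon <- table %>%
    dplyr::group_by(.data$animal_id, .data$axon_id, .data$measure_type) %>%
    dplyr::summarise(mean_um = mean(.data$value_um), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "measure_type", values_from = "mean_um") %>%
    dplyr::mutate(diameter_ratio =
                    if (all(c("internode_diameter", "node_diameter") %in%
                            names(.))) {
                      .data$internode_diameter / .data$node_diameter
                    } else NA_real_)
  per_animal <- per_axon %>%
    dplyr::group_by(.data$animal_id) %>%
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric),
                                   ~ mean(.x, na.rm = TRUE)),
                     n_axons = dplyr::n(), .groups = "drop")
  checks <- table %>%
    dplyr::group_by(.data$animal_id) %>%
    dplyr::summarise(n_measurements = dplyr::n(),
                     n_axons = dplyr::n_distinct(.data$axon_id),
                     .groups = "drop") %>%
    dplyr::mutate(status = dplyr::if_else(
      .data$n_measurements >= 10 & .data$n_axons >= 3, "pass", "warn"))
  if (any(checks$status == "warn")) {
    rlang::warn(paste0(sum(checks$status == "warn"),
                       " animal(s) with <10 measurements or <3 axons"))
  }
  list(per_axon = per_axon, per_animal = per_animal, checks = checks)
}

#' Detect a nodal constriction in a diameter profile
#'
#' Finds the node center as the diameter minimum, estimates the internodal
#' diameter from regions at least 10 um away from it, and measures the
#' constriction length as the width of the contiguous region where the
#' diameter stays below the half-depth level
#' `d_min + fraction * (internode - d_min)` (half-depth rule, fraction 0.5
#' by default), with sub-grid linear interpolation of the two crossings.
#'
#' @param profile Tibble with uniformly sampled `s_um` and `d_um` (> 0),
#'   spanning at least 20 um.
#' @param half_depth_fraction Fraction of the constriction depth defining
#'   the boundary level (default 0.5).
#' @param min_depth_fraction Minimum relative depth
#'   `(internode - d_min) / internode` below which no constriction is
#'   declared (default 0.1).
#' @return A `constriction_fit` list: `node_center_s_um`, `node_diameter_um`,
#'   `internode_diameter_um`, `node_length_um`, `half_depth_level_um`.
#'   Supports [generics::tidy()] and [generics::glance()].
#' @details Diameter ties at the minimum are broken toward the profile
#'   midpoint. Scaling all diameters by a constant scales the returned
#'   diameters and leaves the length unchanged.
#' @export
detect_constriction <- function(profile, half_depth_fraction = 0.5,
                                min_depth_fraction = 0.1) {
  s <- profile$s_um
  d <- profile$d_um
  if (any(d <= 0) || any(!is.finite(d))) {
    rlang::abort("diameters must be positive", class = "nodetrans_validation_error")
  }
  if (diff(range(s)) < 20) {
    rlang::abort("profile must span at least 20 um",
                 class = "nodetrans_validation_error")
  }
  o <- order(s)
  s <- s[o]; d <- d[o]
  d_min <- min(d)
  cand <- which(d <= d_min + 1e-12)
  mid <- (s[1] + s[length(s)]) / 2
  i_min <- cand[which.min(abs(s[cand] - mid))]
  far <- abs(s - s[i_min]) >= 10
  if (!any(far)) {
    rlang::abort("profile too short to estimate the internodal diameter",
                 class = "nodetrans_validation_error")
  }
  d_inter <- mean(d[far])
  depth <- d_inter - d_min
  if (depth < min_depth_fraction * d_inter) {
    rlang::abort("no constriction: relative depth below threshold",
                 class = "nodetrans_constriction_error")
  }
  level <- d_min + half_depth_fraction * depth
  # expand outward from the minimum while the diameter stays at/below level
  j <- i_min
  while (j > 1 && d[j - 1] <= level) j <- j - 1
  s_left <- if (j == 1) s[1] else {
    s[j - 1] + (d[j - 1] - level) / (d[j - 1] - d[j]) * (s[j] - s[j - 1])
  }
  k <- i_min
  n <- length(s)
  while (k < n && d[k + 1] <= level) k <- k + 1
  s_right <- if (k == n) s[n] else {
    s[k] + (d[k] - level) / (d[k] - d[k + 1]) * (s[k + 1] - s[k])
  }
  structure(list(
    node_center_s_um = s[i_min],
    node_diameter_um = d_min,
    internode_diameter_um = d_inter,
    node_length_um = s_right - s_left,
    half_depth_level_um = level
  ), class = "constriction_fit")
}

#' @export
print.constriction_fit <- function(x, ...) {
  cat("<constriction_fit> node ", round(x$node_diameter_um, 2), " um / internode ",
      round(x$internode_diameter_um, 2), " um, length ",
      round(x$node_length_um, 2), " um at s = ",
      round(x$node_center_s_um, 2), "\n", sep = "")
  invisible(x)
}

#' @rdname detect_constriction
#' @param x A `constriction_fit`.
#' @param ... Unused.
#' @method tidy constriction_fit
#' @export
tidy.constriction_fit <- function(x, ...) {
  tibble::tibble(
    node_center_s_um = x$node_center_s_um,
    node_diameter_um = x$node_diameter_um,
    internode_diameter_um = x$internode_diameter_um,
    node_length_um = x$node_length_um,
    half_depth_level_um = x$half_depth_level_um
  )
}

#' @rdname detect_constriction
#' @method glance constriction_fit
#' @export
glance.constriction_fit <- function(x, ...) {
  tibble::tibble(
    node_length_um = x$node_length_um,
    diameter_ratio = x$internode_diameter_um / x$node_diameter_um
  )
}
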