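#' Analysis configuration
#'
#' Bundles the thresholds of the transport-dynamics quantification. Defaults
#' follow the field's standard criteria: a pause is a frame-to-frame
#' interval with apparent speed at or below 0.1 um/s; tracks qualify when
#' they move for at least 10 consecutive steps; terminal pause runs of at
#' least 10 steps are trimmed; movements are binned every 2 um across an
#' 80 um window centered on the node, partitioned 38 / 4 / 38 um into
#' proximal internode, nodal constriction and distal internode.
#'
#' @param pause_speed_threshold Pause speed threshold, um/s.
#' @param min_consecutive_moving_frames Minimum run of consecutive non-pause
#'   steps for a track to qualify.
#' @param terminal_pause_min_frames Minimum length of a terminal pause run
#'   to be trimmed.
#' @param min_tracks_per_axon,min_tracks_per_axon_retro_mito Minimum
#'   qualified tracks per axon (general, and for retrograde mitochondria).
#' @param window_half_width Half-width of the node-centered window, um.
#' @param bin_width Bin width, um; must divide the window exactly.
#' @param internode_length,node_length Lengths of each internodal segment
#'   and of the nodal constriction within the window, um; must satisfy
#'   `2 * internode_length + node_length == 2 * window_half_width`.
#' @param max_gap_frames Frame gaps larger than this split a track in two;
#'   gaps up to this size produce a single spanning step flagged `is_gap`.
#' @param stationary_net_threshold Secondary stationarity criterion for
#'   motility classification: absolute net axial displacement below this
#'   (um) is called stationary even with a qualifying run.
#' @param pause_freq_mode `"per_step"` (default): pause relative frequency
#'   is pauses / steps within a location; `"share_of_pauses"`: pauses in the
#'   location / all pauses.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(pause_speed_threshold = 0.1,
                            min_consecutive_moving_frames = 10,
                            terminal_pause_min_frames = 10,
                            min_tracks_per_axon = 20,
                            min_tracks_per_axon_retro_mito = 10,
                            window_half_width = 40,
                            bin_width = 2,
                            internode_length = 38,
                            node_length = 4,
                            max_gap_frames = 2,
                            stationary_net_threshold = 2,
                            pause_freq_mode = c("per_step", "share_of_pauses")) {
  pause_freq_mode <- match.arg(pause_freq_mode)
  if (abs(2 * internode_length + node_length - 2 * window_half_width) > 1e-9) {
    rlang::abort("2*internode_length + node_length must equal 2*window_half_width",
                 class = "nodetrans_validation_error")
  }
  n_bins <- 2 * window_half_width / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    rlang::abort("bin_width must divide the window exactly",
                 class = "nodetrans_validation_error")
  }
  structure(list(
    pause_speed_threshold = pause_speed_threshold,
    min_consecutive_moving_frames = min_consecutive_moving_frames,
    terminal_pause_min_frames = terminal_pause_min_frames,
    min_tracks_per_axon = min_tracks_per_axon,
    min_tracks_per_axon_retro_mito = min_tracks_per_axon_retro_mito,
    window_half_width = window_half_width,
    bin_width = bin_width,
    internode_length = internode_length,
    node_length = node_length,
    max_gap_frames = max_gap_frames,
    stationary_net_threshold = stationary_net_threshold,
    pause_freq_mode = pause_freq_mode
  ), class = "analysis_config")
}

.step_keys <- c("animal_id", "axon_id", "track_id")

#' Compute frame-to-frame step records
#'
#' Converts projected spots into one record per consecutive spot pair: 2D
#' Euclidean displacement, apparent speed, signed axial displacement, the
#' midpoint axial position `s_mid_um` used for spatial assignment, and a
#' pause flag (`speed <= pause_speed_threshold`). Speed uses the full 2D
#' displacement while location uses the axial coordinate.
#'
#' @param tracks Spot tibble with `s_um` (see [project_to_axis()]).
#' @param config An [analysis_config()].
#' @return A step tibble, one row per frame-to-frame interval.
#' @details Missing intermediate frames up to `max_gap_frames` yield a
#'   single spanning record with the true elapsed `dt_s`, flagged `is_gap`;
#'   larger gaps split the track into independent tracks (suffix `#k` on
#'   `track_id`). Non-positive `dt_s` is a validation error.
#' @export
compute_steps <- function(tracks, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (!"s_um" %in% names(tracks)) {
    rlang::abort("tracks must carry s_um; run project_to_axis() first",
                 class = "nodetrans_validation_error")
  }
  if (!"animal_id" %in% names(tracks)) tracks$animal_id <- "animal1"
  tracks <- dplyr::arrange(tracks, .data$animal_id, .data$axon_id,
                           .data$track_id, .data$frame)
  # split tracks at frame gaps larger than max_gap_frames
  tracks <- tracks %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(.step_keys))) %>%
    dplyr::mutate(
      .piece = cumsum(c(0, diff(.data$frame)) > config$max_gap_frames)
    ) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(track_id = ifelse(.data$.piece > 0,
                                    paste0(.data$track_id, "#", .data$.piece + 1),
                                    .data$track_id)) %>%
    dplyr::select(-".piece")
  carry <- intersect(c("organelle", "video_duration_s", "length_um"),
                     names(tracks))
  steps <- tracks %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c(.step_keys, carry)))) %>%
    dplyr::reframe(
      frame_from = .data$frame[-dplyr::n()],
      frame_to = .data$frame[-1],
      dt_s = diff(.data$t_s),
      displacement_um = sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2),
      axial_delta_um = diff(.data$s_um),
      s_mid_um = (.data$s_um[-dplyr::n()] + .data$s_um[-1]) / 2
    )
  if (nrow(steps) > 0 && any(steps$dt_s <= 0)) {
    rlang::abort("non-positive frame-to-frame dt",
                 class = "nodetrans_validation_error")
  }
  steps %>%
    dplyr::mutate(
      speed_um_s = .data$displacement_um / .data$dt_s,
      is_gap = .data$frame_to - .data$frame_from > 1,
      is_pause = .data$speed_um_s <= config$pause_speed_threshold
    ) %>%
    tibble::as_tibble()
}

#' Trim terminal pauses
#'
#' Removes, from each end of every track's step sequence, maximal runs of
#' consecutive pause steps whose length reaches
#' `terminal_pause_min_frames`; applied from both ends until no such
#' terminal run remains. Interior pause runs of any length are retained.
#' The operation is idempotent and may return an empty step set.
#'
#' @param steps A step tibble from [compute_steps()].
#' @param config An [analysis_config()].
#' @return The step tibble with terminal pause runs removed.
#' @export
trim_terminal_pauses <- function(steps, config = analysis_config()) {
  if (nrow(steps) == 0) return(steps)
  steps %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(.step_keys))) %>%
    dplyr::arrange(.data$frame_from, .by_group = TRUE) %>%
    dplyr::filter(.trim_keep(.data$is_pause, config$terminal_pause_min_frames)) %>%
    dplyr::ungroup()
}

.trim_keep <- function(is_pause, min_len) {
  keep <- rep(TRUE, length(is_pause))
  repeat {
    idx <- which(keep)
    if (length(idx) == 0) break
    r <- rle(is_pause[idx])
    changed <- FALSE
    if (r$values[1] && r$lengths[1] >= min_len) {
      keep[idx[seq_len(r$lengths[1])]] <- FALSE
      changed <- TRUE
    }
    idx <- which(keep)
    if (length(idx) > 0) {
      r <- rle(is_pause[idx])
      k <- length(r$values)
      if (r$values[k] && r$lengths[k] >= min_len) {
        keep[idx[(length(idx) - r$lengths[k] + 1):length(idx)]] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  keep
}

#' Qualify tracks by sustained movement
#'
#' A track qualifies when it contains at least one run of
#' `min_consecutive_moving_frames` consecutive non-pause steps (after
#' terminal-pause trimming). Non-qualifying tracks get a reason code.
#'
#' @param steps A (trimmed) step tibble.
#' @param config An [analysis_config()].
#' @return One row per track: keys, `accepted`, `reason`
#'   (`"ok"`, `"no_qualifying_run"` or `"empty_after_trim"`), and
#'   `max_moving_run`.
#' @export
qualify_tracks <- function(steps, config = analysis_config()) {
  steps %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(.step_keys))) %>%
    dplyr::arrange(.data$frame_from, .by_group = TRUE) %>%
    dplyr::summarise(
      max_moving_run = .max_run(!.data$is_pause),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      accepted = .data$max_moving_run >= config$min_consecutive_moving_frames,
      reason = dplyr::if_else(.data$accepted, "ok", "no_qualifying_run")
    )
}

.max_run <- function(x) {
  if (length(x) == 0 || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Keep only steps of qualified tracks
#'
#' @param steps A (trimmed) step tibble.
#' @param config An [analysis_config()].
#' @return The steps of accepted tracks.
#' @export
filter_qualified <- function(steps, config = analysis_config()) {
  q <- qualify_tracks(steps, config)
  dplyr::semi_join(steps, dplyr::filter(q, .data$accepted), by = .step_keys)
}

#' Check per-axon organelle counts
#'
#' Each axon should contribute a minimum number of trackable organelles: 20
#' in general, 10 for retrogradely moving mitochondria. Below-threshold
#' axons are flagged with a warning by default; set `exclude = TRUE` to also
#' mark them for exclusion.
#'
#' @param qualified Per-track tibble with keys, `organelle` and (optionally)
#'   a `direction` column (`"anterograde"` / `"retrograde"`).
#' @param config An [analysis_config()].
#' @param exclude If `TRUE` the returned tibble's `keep` column is `FALSE`
#'   for failing groups (default: warn only, keep everything).
#' @return One row per (axon, organelle, direction): `n_tracks`,
#'   `required`, `status` (`"pass"`/`"warn"`), `keep`.
#' @export
check_axon_counts <- function(qualified, config = analysis_config(),
                              exclude = FALSE) {
  if (!"direction" %in% names(qualified)) qualified$direction <- NA_character_
  res <- qualified %>%
    dplyr::group_by(.data$animal_id, .data$axon_id, .data$organelle,
                    .data$direction) %>%
    dplyr::summarise(n_tracks = dplyr::n(), .groups = "drop") %>%
    dplyr::mutate(
      required = dplyr::if_else(
        .data$organelle == "mitochondrion" &
          !is.na(.data$direction) & .data$direction == "retrograde",
        config$min_tracks_per_axon_retro_mito,
        config$min_tracks_per_axon),
      status = dplyr::if_else(.data$n_tracks >= .data$required, "pass", "warn"),
      keep = !exclude | .data$status == "pass"
    )
  if (any(res$status == "warn")) {
    rlang::warn(paste0(sum(res$status == "warn"),
                       " axon group(s) below the minimum track count"))
  }
  res
}

#' Assign node-centered bins and subdomains
#'
#' Bins `s_mid_um` into half-open 2-um bins `[-40, +40)` (plus the closing
#' edge at +40) and labels each step's subdomain: proximal internode
#' `[-40, -2)`, nodal constriction `[-2, +2]` (closed on both sides, so
#' steps at exactly +/-2 um belong to the node), distal internode
#' `(+2, +40]`. Steps beyond the window are labelled `"outside"` and are
#' excluded from summaries.
#'
#' @param steps A step tibble.
#' @param config An [analysis_config()].
#' @return The step tibble with `bin_index` (0-based) and `subdomain`.
#' @export
assign_bins <- function(steps, config = analysis_config()) {
  w <- config$window_half_width
  bw <- config$bin_width
  half_node <- config$node_length / 2
  n_bins <- as.integer(round(2 * w / bw))
  s <- steps$s_mid_um
  bin <- floor((s + w) / bw)
  bin[s == w] <- n_bins - 1
  outside <- s < -w | s > w
  bin[outside] <- NA_integer_
  steps$bin_index <- as.integer(bin)
  steps$subdomain <- dplyr::case_when(
    outside ~ "outside",
    abs(s) <= half_node ~ "center",
    s < -half_node ~ "proximal",
    TRUE ~ "distal"
  )
  steps$subdomain <- factor(steps$subdomain,
                            levels = c("proximal", "center", "distal", "outside"))
  steps
}

#' Summarize kinematics per location
#'
#' For each bin or subdomain (optionally within extra grouping keys such as
#' axon or animal) computes the number of steps, the number of pauses, the
#' pause relative frequency and the mean moving velocity (mean of apparent
#' speeds over non-pause steps; `NA` where a location holds no moving
#' steps). Steps outside the window are dropped.
#'
#' @param steps A binned step tibble (see [assign_bins()]).
#' @param config An [analysis_config()].
#' @param by `"subdomain"` (default) or `"bin"`.
#' @param groups Character vector of extra grouping columns (e.g.
#'   `c("animal_id", "axon_id")`); `NULL` pools everything.
#' @return A tibble with one row per location (x group).
#' @export
summarize_kinematics <- function(steps, config = analysis_config(),
                                 by = c("subdomain", "bin"), groups = NULL) {
  by <- match.arg(by)
  steps <- dplyr::filter(steps, .data$subdomain != "outside")
  loc <- if (by == "subdomain") "subdomain" else "bin_index"
  out <- steps %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c(groups, loc)))) %>%
    dplyr::summarise(
      n_steps = dplyr::n(),
      n_pauses = sum(.data$is_pause),
      mean_moving_velocity = if (any(!.data$is_pause))
        mean(.data$speed_um_s[!.data$is_pause]) else NA_real_,
      .groups = "drop_last"
    )
  out <- if (config$pause_freq_mode == "per_step") {
    dplyr::mutate(out, pause_relative_frequency = .data$n_pauses / .data$n_steps)
  } else {
    dplyr::mutate(out, pause_relative_frequency =
                    .data$n_pauses / sum(.data$n_pauses))
  }
  out <- dplyr::ungroup(out)
  if (by == "bin") {
    out$bin_center_um <- -config$window_half_width +
      (out$bin_index + 0.5) * config$bin_width
  }
  out
}

#' Pearson correlation between per-axon transport statistics and diameter
#'
#' Standard two-tailed Pearson correlation, e.g. between per-axon mean
#' moving velocity (or pause frequency) and mean axonal diameter. The p
#' value follows from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param data A data frame of per-axon values.
#' @param x,y Columns to correlate (tidy evaluation).
#' @return A one-row tibble: `n`, `r`, `p_value`.
#' @export
pearson_speed_diameter <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) {
    rlang::abort("Pearson correlation requires at least 3 complete pairs",
                 class = "nodetrans_validation_error")
  }
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    rlang::abort("Pearson correlation undefined for constant input",
                 class = "nodetrans_validation_error")
  }
  ct <- stats::cor.test(xv, yv, method = "pearson", alternative = "two.sided")
  tibble::tibble(n = length(xv), r = unname(ct$estimate),
                 p_value = ct$p.value)
}

#' End-to-end node-centered kinematics
#'
#' Runs the full quantification on raw tracks: projection onto the axon,
#' step computation, terminal-pause trimming, qualification, binning, and
#' per-subdomain / per-bin summaries, plus the percent-change quantities
#' comparing the nodal constriction with the internodes.
#'
#' @param tracks Raw spot tibble.
#' @param geometry An [axon_geometry()].
#' @param config An [analysis_config()].
#' @return A `node_kinematics` object with elements `steps` (qualified,
#'   binned), `qualification`, `bins`, `subdomains`, `percent_changes` and
#'   `config`. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
node_kinematics <- function(tracks, geometry, config = analysis_config()) {
  proj <- project_to_axis(tracks, geometry)
  steps <- compute_steps(proj, config)
  trimmed <- trim_terminal_pauses(steps, config)
  qual <- qualify_tracks(trimmed, config)
  kept <- filter_qualified(trimmed, config)
  binned <- assign_bins(kept, config)
  subdomains <- summarize_kinematics(binned, config, by = "subdomain")
  bins <- summarize_kinematics(binned, config, by = "bin")
  structure(list(
    steps = binned,
    qualification = qual,
    bins = bins,
    subdomains = subdomains,
    percent_changes = percent_changes(subdomains),
    config = config
  ), class = "node_kinematics")
}

#' Percent-change summary of subdomain kinematics
#'
#' Derives the standard effect-size quantities from a per-subdomain
#' summary: percent reduction of nodal mean moving velocity relative to
#' each internode, percent excess of proximal over distal velocity, and
#' percent reduction of internodal pause frequency relative to the node
#' (e.g. `100 * (1 - v_node / v_proximal)`).
#'
#' @param subdomains A subdomain summary from [summarize_kinematics()]
#'   (pooled, i.e. without extra grouping).
#' @return A one-row tibble of percent changes.
#' @export
percent_changes <- function(subdomains) {
  g <- function(dom, col) {
    v <- subdomains[[col]][subdomains$subdomain == dom]
    if (length(v) == 0) NA_real_ else v[1]
  }
  v_p <- g("proximal", "mean_moving_velocity")
  v_c <- g("center", "mean_moving_velocity")
  v_d <- g("distal", "mean_moving_velocity")
  p_p <- g("proximal", "pause_relative_frequency")
  p_c <- g("center", "pause_relative_frequency")
  p_d <- g("distal", "pause_relative_frequency")
  tibble::tibble(
    velocity_node_vs_proximal_pct = 100 * (1 - v_c / v_p),
    velocity_node_vs_distal_pct = 100 * (1 - v_c / v_d),
    velocity_proximal_vs_distal_excess_pct = 100 * (v_p / v_d - 1),
    pause_proximal_vs_node_reduction_pct = 100 * (1 - p_p / p_c),
    pause_distal_vs_node_reduction_pct = 100 * (1 - p_d / p_c)
  )
}

#' @export
print.node_kinematics <- function(x, ...) {
  cat("<node_kinematics> ", nrow(x$qualification), " tracks (",
      sum(x$qualification$accepted), " qualified), ",
      nrow(x$steps), " in-window steps\n", sep = "")
  print(x$subdomains)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a node_kinematics object
#'
#' @param x A `node_kinematics` object.
#' @param by `"subdomain"` or `"bin"`.
#' @param ... Unused.
#' @return The per-location summary tibble.
#' @method tidy node_kinematics
#' @export
tidy.node_kinematics <- function(x, by = c("subdomain", "bin"), ...) {
  by <- match.arg(by)
  if (by == "subdomain") x$subdomains else x$bins
}

#' One-row summary of a node_kinematics object
#'
#' @param x A `node_kinematics` object.
#' @param ... Unused.
#' @return A one-row tibble: track counts and percent-change quantities.
#' @method glance node_kinematics
#' @export
glance.node_kinematics <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      n_tracks = nrow(x$qualification),
      n_qualified = sum(x$qualification$accepted),
      n_steps = nrow(x$steps)
    ),
    x$percent_changes
  )
}
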