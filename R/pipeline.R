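#' Hierarchical axon-to-animal aggregation
#'
#' Implements the study's reporting convention: values are first averaged
#' within each axon, then the unweighted mean of axon means is taken per
#' animal. Warns when an animal contributes fewer than `min_axons` axons.
#'
#' @param data A data frame of per-step or per-track values.
#' @param value Column to aggregate (tidy evaluation).
#' @param groups Extra grouping columns kept through both levels (e.g.
#'   `"subdomain"`).
#' @param min_axons Minimum axons per animal before warning (default 3).
#' @return A tibble per (animal x groups): `mean_value`, `n_axons`.
#' @export
aggregate_hierarchy <- function(data, value, groups = NULL, min_axons = 3) {
  per_axon <- data %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("animal_id", groups, "axon_id")))) %>%
    dplyr::summarise(.axon_mean = mean({{ value }}, na.rm = TRUE),
                     .groups = "drop")
  out <- per_axon %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c("animal_id", groups)))) %>%
    dplyr::summarise(mean_value = mean(.data$.axon_mean),
                     n_axons = dplyr::n(), .groups = "drop")
  low <- dplyr::distinct(out, .data$animal_id, .data$n_axons) %>%
    dplyr::group_by(.data$animal_id) %>%
    dplyr::summarise(n = max(.data$n_axons), .groups = "drop")
  if (any(low$n < min_axons)) {
    rlang::warn(paste0(sum(low$n < min_axons),
                       " animal(s) with fewer than ", min_axons, " axons"))
  }
  out
}

#' Run a pipeline stage and write its outputs
#'
#' Deterministic file-based front end over the analysis functions. Each
#' invocation writes its tables plus a `manifest.json` recording the
#' configuration snapshot, input file hashes, seed, package version and a
#' timestamp; partial outputs are removed on failure.
#'
#' @param command One of `"simulate"`, `"kinematics"`, `"flux"`,
#'   `"profile"`, `"morphometry"`, `"report"`.
#' @param config A named list. `simulate` takes `preset` (and generator
#'   overrides); `kinematics` / `flux` take `input` (a directory produced
#'   by `simulate`, or explicit `tracks` / `geometry` paths) and optional
#'   [analysis_config()] overrides under `analysis`; `profile` takes
#'   `input` (profiles TSV with columns `axon_id`, `s_um`, `F`) and
#'   optional `background`; `morphometry` takes `input` (diameter profile
#'   TSV `s_um`, `d_um`); `report` takes `input` (directory holding
#'   `kinematics`/`flux` outputs).
#' @param out_dir Output directory (created; must be empty or absent unless
#'   `overwrite`).
#' @param seed Seed recorded in the manifest and used by `simulate`.
#' @param overwrite Allow writing into an existing directory.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(command, config = list(), out_dir, seed = 1L,
                         overwrite = FALSE) {
  commands <- c("simulate", "kinematics", "flux", "profile", "morphometry",
                "report")
  if (!command %in% commands) {
    rlang::abort(paste0("unknown command: ", command,
                        " (expected one of ", paste(commands, collapse = ", "), ")"),
                 class = "nodetrans_validation_error")
  }
  if (dir.exists(out_dir) && !overwrite &&
      length(list.files(out_dir)) > 0) {
    rlang::abort(paste0("output directory not empty: ", out_dir),
                 class = "nodetrans_io_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(df, p, progress = FALSE)
    written <<- c(written, p)
    p
  }
  inputs <- character(0)
  ok <- tryCatch({
    switch(command,
      simulate = {
        preset <- config$preset %||% "endosome_paper"
        over <- config[setdiff(names(config), c("preset", "analysis", "input"))]
        gc_ <- do.call(generator_config,
                       c(list(preset = preset, seed = seed), over))
        sim <- simulate_tracks(gc_)
        write_tracks_csv(sim$tracks, file.path(out_dir, "tracks.csv"))
        written <- c(written, file.path(out_dir, "tracks.csv"))
        write_axon_geometry(sim$geometry, file.path(out_dir, "geometry.json"))
        emit(sim$truth$tracks, "truth_tracks.tsv")
        emit(sim$truth$steps, "truth_steps.tsv")
      },
      kinematics = {
        io <- .pipeline_inputs(config)
        inputs <- c(io$tracks_path, io$geometry_path)
        cfg <- do.call(analysis_config, config$analysis %||% list())
        nk <- node_kinematics(io$tracks, io$geometry, cfg)
        emit(nk$steps, "steps.tsv")
        emit(nk$qualification, "qualification.tsv")
        emit(nk$bins, "bin_profile.tsv")
        emit(nk$subdomains, "subdomain_summary.tsv")
        emit(nk$percent_changes, "percent_changes.tsv")
      },
      flux = {
        io <- .pipeline_inputs(config)
        inputs <- c(io$tracks_path, io$geometry_path)
        cfg <- do.call(analysis_config, config$analysis %||% list())
        proj <- project_to_axis(io$tracks, io$geometry)
        steps <- assign_bins(
          trim_terminal_pauses(compute_steps(proj, cfg), cfg), cfg)
        labels <- classify_motility(steps, cfg)
        counts <- count_directional_movements(steps, labels)
        flux <- flux_per_minute(counts)
        emit(labels, "labels.tsv")
        emit(flux, "flux.tsv")
        emit(pool_flux(flux), "flux_pooled.tsv")
        emit(direction_fraction(labels), "direction_fractions.tsv")
        if ("length_um" %in% names(steps) && any(!is.na(steps$length_um))) {
          emit(length_summary(steps, labels), "length_summary.tsv")
        }
      },
      profile = {
        path <- config$input
        if (is.null(path) || !file.exists(path)) {
          rlang::abort("profile command needs an input TSV",
                       class = "nodetrans_io_error")
        }
        inputs <- path
        prof <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
        sub <- if (!is.null(config$background)) {
          subtract_background(prof, method = "value",
                              value = config$background)
        } else subtract_background(prof)
        rel <- normalize_relative(sub)
        avg <- average_profile(rel)
        emit(rel, "relative_profiles.tsv")
        emit(avg, "average_profile.tsv")
        emit(peak_metrics(avg), "peak_metrics.tsv")
        emit(mirrored_region_stats(rel, config$range_um %||% c(1, 11)),
             "mirrored_stats.tsv")
      },
      morphometry = {
        path <- config$input
        if (is.null(path) || !file.exists(path)) {
          rlang::abort("morphometry command needs an input TSV",
                       class = "nodetrans_io_error")
        }
        inputs <- path
        prof <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
        emit(tidy(detect_constriction(prof)), "constriction.tsv")
      },
      report = {
        dir_in <- config$input
        need <- file.path(dir_in, c("subdomain_summary.tsv",
                                    "percent_changes.tsv"))
        if (is.null(dir_in) || !all(file.exists(need))) {
          rlang::abort("report command needs a directory with kinematics outputs",
                       class = "nodetrans_io_error")
        }
        inputs <- need
        sub <- readr::read_tsv(need[1], show_col_types = FALSE, progress = FALSE)
        pct <- readr::read_tsv(need[2], show_col_types = FALSE, progress = FALSE)
        report <- dplyr::bind_cols(
          tidyr::pivot_wider(
            dplyr::select(sub, "subdomain", "mean_moving_velocity",
                          "pause_relative_frequency"),
            names_from = "subdomain",
            values_from = c("mean_moving_velocity", "pause_relative_frequency")),
          pct)
        for (extra in c("flux_pooled.tsv", "direction_fractions.tsv",
                        "length_summary.tsv", "peak_metrics.tsv",
                        "constriction.tsv")) {
          p <- file.path(dir_in, extra)
          if (file.exists(p)) {
            file.copy(p, file.path(out_dir, extra), overwrite = TRUE)
            written <- c(written, file.path(out_dir, extra))
          }
        }
        emit(report, "report.tsv")
      })
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    unlink(written)
    rlang::abort(paste0("pipeline stage '", command, "' failed: ",
                        conditionMessage(ok)),
                 parent = ok, class = "nodetrans_pipeline_error")
  }
  manifest <- list(
    command = command,
    config = config[setdiff(names(config), "tracks")],
    seed = seed,
    inputs = as.list(stats::setNames(
      as.character(tools::md5sum(inputs[file.exists(inputs)])),
      inputs[file.exists(inputs)])),
    package = "nodetrans",
    version = as.character(utils::packageVersion("nodetrans")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

.pipeline_inputs <- function(config) {
  if (!is.null(config$input) && dir.exists(config$input)) {
    tracks_path <- file.path(config$input, "tracks.csv")
    geometry_path <- file.path(config$input, "geometry.json")
  } else {
    tracks_path <- config$tracks
    geometry_path <- config$geometry
  }
  if (is.null(tracks_path) || !file.exists(tracks_path) ||
      is.null(geometry_path) || !file.exists(geometry_path)) {
    rlang::abort("input tracks/geometry not found",
                 class = "nodetrans_io_error")
  }
  list(tracks = read_tracks_csv(tracks_path),
       geometry = read_axon_geometry(geometry_path),
       tracks_path = tracks_path, geometry_path = geometry_path)
}

#' Plot a node-centered kinematic profile
#'
#' Mean moving velocity (line) and pause relative frequency (bars) per
#' 2-um bin against the signed distance from the node center.
#'
#' @param object A `node_kinematics` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot node_kinematics
#' @export
autoplot.node_kinematics <- function(object, ...) {
  bins <- object$bins
  vmax <- max(bins$mean_moving_velocity, na.rm = TRUE)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin_center_um)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$pause_relative_frequency * vmax),
                      fill = "grey70", width = object$config$bin_width * 0.9) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_moving_velocity),
                       colour = "purple", na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_moving_velocity),
                        colour = "purple", na.rm = TRUE) +
    ggplot2::scale_y_continuous(
      name = "Mean moving velocity (µm/s)",
      sec.axis = ggplot2::sec_axis(~ . / vmax,
                                   name = "Pause relative frequency")) +
    ggplot2::labs(x = "Distance from node center (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a diameter profile with its constriction fit
#'
#' @param profile Tibble `s_um`, `d_um`.
#' @param fit A `constriction_fit` from [detect_constriction()].
#' @return A ggplot.
#' @export
plot_constriction <- function(profile, fit) {
  half <- fit$node_length_um / 2
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$s_um, y = .data$d_um)) +
    ggplot2::geom_line() +
    ggplot2::annotate("rect", xmin = fit$node_center_s_um - half,
                      xmax = fit$node_center_s_um + half,
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::geom_hline(yintercept = fit$half_depth_level_um,
                        linetype = "dashed") +
    ggplot2::labs(x = "Position (µm)", y = "Diameter (µm)") +
    ggplot2::theme_minimal()
}
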