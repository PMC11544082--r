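.generator_presets <- c("endosome_paper", "endosome_soleus_paper", "mito_paper",
                        "accumulation_paper", "morphometry_paper", "null_uniform")

#' Build a generator configuration
#'
#' Returns a fully populated configuration for the stochastic transport
#' simulator. Named presets encode the study conditions the package is
#' validated against: region-dependent moving speeds and pause
#' probabilities whose ratios equal the printed effect sizes, acquisition
#' frame intervals (0.5 s endosomes, 1.7 s mitochondria), an anterograde
#' mitochondrial majority, a distal stationary cluster, a distal
#' fluorescence accumulation and a 4-um nodal constriction.
#'
#' @param preset One of `"endosome_paper"` (retrograde endosomes,
#'   TA-innervating axons), `"endosome_soleus_paper"`, `"mito_paper"`,
#'   `"accumulation_paper"`, `"morphometry_paper"`, `"null_uniform"`
#'   (identical parameters in all regions; negative control).
#' @param seed Integer seed fixing all generator output.
#' @param ... Named overrides of any configuration field.
#' @return A `generator_config` list.
#' @details Speed means/pause probabilities are named vectors
#'   `c(proximal, node, distal)` per direction. Key preset constants:
#'   `endosome_paper` speeds 2.40 / 1.25 / 2.10 um/s (SD 0.25), pause
#'   probabilities 0.042 / 0.30 / 0.099; `endosome_soleus_paper` speeds
#'   2.41 / 1.30 / 2.00; `mito_paper` anterograde 0.500 / 0.360 / 0.456 and
#'   retrograde 0.500 / 0.380 / 0.494 um/s (SD 0.05), anterograde fraction
#'   0.76, anterograde pause probability 0.20 at the node vs 0.12 in the
#'   internodes, stationary mitochondria mean length 1.8 um vs motile
#'   1.1 um; `accumulation_paper` flat baseline 1.0 plus a Gaussian bump of
#'   amplitude 0.5 centered +3.75 um distal (SD 2.0 um), multiplicative
#'   noise SD 0.1; `morphometry_paper` internode 3.0 um, node 1.4 um,
#'   length 4.0 um, 5% noise.
#' @export
generator_config <- function(preset = "endosome_paper", seed = 1L, ...) {
  if (!preset %in% .generator_presets) {
    rlang::abort(paste0("unknown preset: ", preset,
                        " (known: ", paste(.generator_presets, collapse = ", "), ")"),
                 class = "nodetrans_validation_error")
  }
  reg <- function(p, n, d) c(proximal = p, node = n, distal = d)
  cfg <- list(
    preset = preset,
    seed = as.integer(seed),
    organelle = "endosome",
    n_tracks = 300L,
    n_stationary = 20L,
    frame_interval_s = 0.5,
    n_frames = 150L,
    speed_means = list(retrograde = reg(2.40, 1.25, 2.10)),
    speed_sd = 0.25,
    speed_floor = 0.15,
    pause_prob = list(retrograde = reg(0.042, 0.30, 0.099)),
    pause_model = "iid_bernoulli",
    pause_run_mean = 3,
    localization_noise_sd = 0.01,
    anterograde_fraction = NA_real_,
    stationary_cluster = list(center_s = 3.75, sd = 2.0),
    length_model = list(stationary_mean = 1.8, motile_mean = 1.1, sd = 0.3),
    axon = list(length = 100, internode_diameter = 3.0, node_diameter = 1.4,
                node_length = 4.0, noise_sd = 0.05, flank_width = 2.0,
                span = 40, grid = 0.1),
    accumulation = list(baseline = 1.0, amplitude = 0.5, center = 3.75,
                        sd = 2.0, noise_sd = 0.1, background = 0.5,
                        grid = 0.5, window = 40),
    lateral_funneling = FALSE,
    n_animals = 5L,
    axons_per_animal = 3L,
    start_range = c(-45, 45),
    stop_margin = 2,
    pause_speed_threshold = 0.1
  )
  if (preset == "endosome_soleus_paper") {
    cfg$speed_means <- list(retrograde = reg(2.41, 1.30, 2.00))
  } else if (preset == "mito_paper") {
    cfg$organelle <- "mitochondrion"
    cfg$frame_interval_s <- 1.7
    cfg$n_frames <- 200L
    cfg$n_stationary <- 40L
    cfg$anterograde_fraction <- 0.76
    cfg$speed_means <- list(anterograde = reg(0.500, 0.360, 0.456),
                            retrograde = reg(0.500, 0.380, 0.494))
    cfg$speed_sd <- 0.05
    cfg$pause_prob <- list(anterograde = reg(0.12, 0.20, 0.12),
                           retrograde = reg(0.12, 0.12, 0.12))
  } else if (preset == "null_uniform") {
    cfg$speed_means <- list(retrograde = reg(2.2, 2.2, 2.2))
    cfg$pause_prob <- list(retrograde = reg(0.10, 0.10, 0.10))
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown config field(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "nodetrans_validation_error")
  }
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  validate_generator_config(structure(cfg, class = "generator_config"))
}

#' @rdname generator_config
#' @param config A `generator_config` to validate.
#' @export
validate_generator_config <- function(config) {
  probs <- unlist(config$pause_prob)
  if (any(probs < 0 | probs > 1)) {
    rlang::abort("pause probabilities must lie in [0, 1]",
                 class = "nodetrans_validation_error")
  }
  speeds <- unlist(config$speed_means)
  # noise-induced apparent speed of a truly paused organelle: the mean 2D
  # displacement of two isotropic localizations, Rayleigh with scale
  # sqrt(2) * noise_sd, divided by the frame interval
  noise_speed <- sqrt(2) * config$localization_noise_sd * sqrt(pi / 2) /
    config$frame_interval_s
  if (any(speeds <= config$pause_speed_threshold + 5 * noise_speed)) {
    rlang::abort("programmed speeds too close to the pause threshold",
                 class = "nodetrans_validation_error")
  }
  if (config$n_frames < 2 || config$n_tracks < 1) {
    rlang::abort("need n_frames >= 2 and n_tracks >= 1",
                 class = "nodetrans_validation_error")
  }
  config
}

# generator region of a signed axial position (speeds/pauses beyond the
# 80-um window extrapolate the adjacent internode)
.region_index <- function(s, half_node) {
  ifelse(abs(s) <= half_node, 2L, ifelse(s < 0, 1L, 3L))
}

# local axon radius from the raised-cosine constriction model
.axon_radius <- function(s, axon) {
  a <- axon$node_length / 2 - axon$flank_width / 2
  u <- abs(s)
  w <- ifelse(u <= a, 1,
              ifelse(u <= a + axon$flank_width,
                     0.5 * (1 + cos(pi * (u - a) / axon$flank_width)), 0))
  (axon$internode_diameter -
      (axon$internode_diameter - axon$node_diameter) * w) / 2
}

.rtruncnorm <- function(n, mean, sd, lower) {
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

#' Simulate organelle tracks
#'
#' Generates time-lapse tracks under a state-switching transport model:
#' each motile organelle starts at a uniform axial position, and at every
#' frame either pauses (zero displacement) with a region-dependent
#' probability, or advances along the axon by a truncated-normal speed draw
#' whose mean depends on the region (proximal internode / nodal
#' constriction / distal internode) of its current position. Stationary
#' organelles are placed from a Gaussian cluster distal to the node and
#' only jitter by localization noise. Emitted (x, y) positions carry
#' isotropic Gaussian localization noise. The same configuration (and
#' seed) reproduces the dataset exactly.
#'
#' @param config A [generator_config()].
#' @return A `sim_tracks` list: `tracks` (spot tibble in the package
#'   dialect), `geometry` ([axon_geometry()]; straight centerline with the
#'   node at its middle), and `truth` (per-track directions, per-step true
#'   pause flags and region indices, the configuration, and the measured
#'   rate at which true pauses exceed the apparent-speed pause threshold,
#'   asserted below 1%).
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  dt <- config$frame_interval_s
  half_node <- config$axon$node_length / 2
  node_x <- config$axon$length / 2
  stop_s <- node_x - config$stop_margin
  n_frames <- config$n_frames
  directions <- names(config$speed_means)

  n <- config$n_tracks
  dir_lab <- if (config$organelle == "mitochondrion" &&
                 !is.na(config$anterograde_fraction)) {
    ifelse(stats::runif(n) < config$anterograde_fraction,
           "anterograde", "retrograde")
  } else rep(directions[1], n)
  dir_sign <- ifelse(dir_lab == "anterograde", 1, -1)
  speed_mat <- do.call(rbind, config$speed_means)   # direction x region
  pause_mat <- do.call(rbind, config$pause_prob)
  dir_row <- match(dir_lab, rownames(speed_mat))

  s0 <- stats::runif(n, config$start_range[1], config$start_range[2])
  S <- matrix(NA_real_, n, n_frames)
  S[, 1] <- s0
  true_pause <- matrix(NA, n, n_frames - 1)
  region_rec <- matrix(NA_integer_, n, n_frames - 1)
  pause_state <- rep(FALSE, n)
  for (k in 2:n_frames) {
    cur <- S[, k - 1]
    reg <- .region_index(cur, half_node)
    p <- pause_mat[cbind(dir_row, reg)]
    if (config$pause_model == "iid_bernoulli") {
      paused <- stats::runif(n) < p
    } else {
      # two-state Markov chain with mean pause run length pause_run_mean and
      # stationary pause fraction equal to the programmed probability
      x <- 1 / config$pause_run_mean
      e <- pmin(p * x / pmax(1 - p, 1e-12), 1)
      u <- stats::runif(n)
      paused <- ifelse(pause_state, u >= x, u < e)
      pause_state <- paused
    }
    v <- .rtruncnorm(n, speed_mat[cbind(dir_row, reg)], config$speed_sd,
                     config$speed_floor)
    S[, k] <- cur + ifelse(paused, 0, dir_sign * v * dt)
    true_pause[, k - 1] <- paused
    region_rec[, k - 1] <- reg
  }

  n_axons <- config$n_animals * config$axons_per_animal
  axon_of <- function(i) ((i - 1L) %% n_axons) + 1L
  u_lat <- stats::runif(n, -0.8, 0.8)

  n_stat <- config$n_stationary
  s_stat <- if (n_stat > 0) {
    pmin(pmax(stats::rnorm(n_stat, config$stationary_cluster$center_s,
                           config$stationary_cluster$sd), -stop_s), stop_s)
  } else numeric(0)

  has_len <- config$organelle == "mitochondrion"
  len_motile <- if (has_len) {
    pmax(stats::rnorm(n, config$length_model$motile_mean,
                      config$length_model$sd), 0.2)
  } else rep(NA_real_, n)
  len_stat <- if (has_len && n_stat > 0) {
    pmax(stats::rnorm(n_stat, config$length_model$stationary_mean,
                      config$length_model$sd), 0.2)
  } else rep(NA_real_, n_stat)

  spots_list <- vector("list", n + n_stat)
  truth_steps <- vector("list", n)
  track_meta <- vector("list", n + n_stat)
  for (i in seq_len(n)) {
    s_i <- S[i, ]
    out <- which(abs(s_i) > stop_s)
    last <- if (length(out) > 0) out[1] - 1L else n_frames
    if (last < 2) last <- 2L  # keep the minimal 2-spot track
    idx <- seq_len(last)
    lat <- if (config$lateral_funneling) {
      u_lat[i] * .axon_radius(s_i[idx], config$axon)
    } else rep(0, last)
    tid <- sprintf("trk%04d", i)
    ax <- axon_of(i)
    spots_list[[i]] <- tibble::tibble(
      animal_id = sprintf("m%02d", ((ax - 1L) %/% config$axons_per_animal) + 1L),
      axon_id = sprintf("a%02d", ax),
      track_id = tid,
      frame = idx - 1L,
      t_s = (idx - 1L) * dt,
      x_um = node_x + s_i[idx],
      y_um = lat,
      organelle = config$organelle,
      length_um = len_motile[i],
      video_duration_s = n_frames * dt
    )
    truth_steps[[i]] <- tibble::tibble(
      track_id = tid,
      frame_from = idx[-last] - 1L,
      true_pause = true_pause[i, seq_len(last - 1L)],
      region = c("proximal", "node", "distal")[region_rec[i, seq_len(last - 1L)]]
    )
    track_meta[[i]] <- tibble::tibble(
      track_id = tid, direction = dir_lab[i], s0 = s0[i],
      stationary = FALSE, length_um = len_motile[i])
  }
  for (j in seq_len(n_stat)) {
    tid <- sprintf("stat%04d", j)
    ax <- axon_of(n + j)
    spots_list[[n + j]] <- tibble::tibble(
      animal_id = sprintf("m%02d", ((ax - 1L) %/% config$axons_per_animal) + 1L),
      axon_id = sprintf("a%02d", ax),
      track_id = tid,
      frame = 0:(n_frames - 1L),
      t_s = (0:(n_frames - 1L)) * dt,
      x_um = node_x + s_stat[j],
      y_um = 0,
      organelle = config$organelle,
      length_um = len_stat[j],
      video_duration_s = n_frames * dt
    )
    track_meta[[n + j]] <- tibble::tibble(
      track_id = tid, direction = "stationary", s0 = s_stat[j],
      stationary = TRUE, length_um = len_stat[j])
  }
  spots <- dplyr::bind_rows(spots_list)
  noise <- config$localization_noise_sd
  spots$x_um <- spots$x_um + stats::rnorm(nrow(spots), 0, noise)
  spots$y_um <- spots$y_um + stats::rnorm(nrow(spots), 0, noise)

  geometry <- axon_geometry(rbind(c(0, 0), c(config$axon$length, 0)),
                            node_center_arclength = node_x, distal_sign = 1)
  truth_tracks <- dplyr::bind_rows(track_meta)
  truth_tracks <- dplyr::left_join(
    truth_tracks,
    dplyr::distinct(spots, .data$track_id, .data$animal_id, .data$axon_id),
    by = "track_id")
  truth_step_tbl <- dplyr::bind_rows(truth_steps)

  # calibration: fraction of true-pause steps whose apparent (noisy) speed
  # exceeds the pause threshold must stay below 1%
  app <- spots %>%
    dplyr::group_by(.data$track_id) %>%
    dplyr::arrange(.data$frame, .by_group = TRUE) %>%
    dplyr::reframe(frame_from = .data$frame[-dplyr::n()],
                   speed = sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2) /
                     diff(.data$t_s)) %>%
    dplyr::inner_join(truth_step_tbl, by = c("track_id", "frame_from"))
  viol <- if (any(app$true_pause)) {
    mean(app$speed[app$true_pause] > config$pause_speed_threshold)
  } else 0
  if (viol >= 0.01) {
    rlang::warn(paste0("localization noise confounds pause detection: ",
                       round(100 * viol, 2), "% of true pauses read as moving"))
  }

  structure(list(
    tracks = spots,
    geometry = geometry,
    truth = list(tracks = truth_tracks, steps = truth_step_tbl,
                 config = config, pause_speed_violation_rate = viol)
  ), class = "sim_tracks")
}

#' @export
print.sim_tracks <- function(x, ...) {
  cat("<sim_tracks> preset ", x$truth$config$preset, ": ",
      dplyr::n_distinct(x$tracks$track_id), " tracks, ",
      nrow(x$tracks), " spots\n", sep = "")
  invisible(x)
}

#' Simulate fluorescence line profiles
#'
#' Generates per-axon line profiles of time-projected fluorescence with a
#' flat axonal baseline, a Gaussian accumulation bump distal to the node,
#' an additive instrument background pedestal, and multiplicative
#' (lognormal, unit-mean) noise:
#' `F_raw(s) = (background + baseline * (1 + amp * exp(-(s - c)^2 / (2 sd^2)))) * noise`.
#' The noise-free expectation is returned alongside.
#'
#' @param config A [generator_config()] (fields under `accumulation`).
#' @param n_axons Number of profiles to draw.
#' @return A list: `profiles` (tibble `axon_id`, `s_um`, `F`),
#'   `expectation` (noise-free raw and signal-only curves) and
#'   `background` (the pedestal, the value a real experiment would measure
#'   off-axon and subtract).
#' @export
simulate_profiles <- function(config, n_axons = 20) {
  stopifnot(inherits(config, "generator_config"))
  acc <- config$accumulation
  set.seed(config$seed)
  s <- seq(-acc$window, acc$window, by = acc$grid)
  signal <- acc$baseline *
    (1 + acc$amplitude * exp(-(s - acc$center)^2 / (2 * acc$sd^2)))
  sdlog <- acc$noise_sd
  profiles <- purrr::map_dfr(seq_len(n_axons), function(i) {
    eta <- stats::rlnorm(length(s), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    tibble::tibble(animal_id = sprintf("m%02d", ((i - 1) %/% 4) + 1),
                   axon_id = sprintf("a%02d", i),
                   s_um = s,
                   F = (acc$background + signal) * eta)
  })
  list(
    profiles = profiles,
    expectation = tibble::tibble(s_um = s, F_raw = acc$background + signal,
                                 F_signal = signal),
    background = acc$background
  )
}

#' Simulate a diameter profile with a nodal constriction
#'
#' Builds a smooth constriction with raised-cosine flanks whose full width
#' at half depth equals the programmed node length, plus optional
#' multiplicative Gaussian noise.
#'
#' @param config A [generator_config()] (fields under `axon`).
#' @return A tibble `s_um`, `d_um` (uniform grid), with the programmed
#'   parameters attached as the `truth` attribute.
#' @export
simulate_diameter_profile <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  ax <- config$axon
  set.seed(config$seed)
  s <- seq(-ax$span / 2, ax$span / 2, by = ax$grid)
  d <- 2 * .axon_radius(s, ax)
  if (ax$noise_sd > 0) {
    d <- d * (1 + stats::rnorm(length(s), 0, ax$noise_sd))
  }
  out <- tibble::tibble(s_um = s, d_um = pmax(d, 1e-3))
  attr(out, "truth") <- list(internode_diameter = ax$internode_diameter,
                             node_diameter = ax$node_diameter,
                             node_length = ax$node_length)
  out
}
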