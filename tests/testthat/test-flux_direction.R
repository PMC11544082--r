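cfg <- analysis_config()

test_that("motility classification covers drift, jitter and random walks", {
  # monotone +15 um drift -> anterograde
  drift <- make_steps(rep(1.5, 20), dir = 1)
  expect_equal(as.character(classify_motility(drift, cfg)$label), "anterograde")
  # moving runs of at most 4 steps -> stationary
  jitter <- make_steps(rep(c(2, 2, 2, 2, 0.05, 0.05), 5),
                       dir = 1)
  jitter$axial_delta_um <- jitter$axial_delta_um *
    rep(c(1, -1), length.out = 30)
  expect_equal(as.character(classify_motility(jitter, cfg)$label), "stationary")
  # random walks: label must equal the sign of the summed moving axial deltas
  set.seed(21)
  for (i in 1:10) {
    sp <- ifelse(runif(40) < 0.2, 0.05, runif(40, 0.5, 2))
    st <- make_steps(sp, dir = 1)
    signs <- sample(c(-1, 1), 40, replace = TRUE)
    st$axial_delta_um <- st$axial_delta_um * signs
    lab <- classify_motility(st, cfg)
    net <- sum(st$axial_delta_um[!st$is_pause])
    if (qualify_tracks(st, cfg)$accepted && abs(net) >= 2) {
      expect_equal(as.character(lab$label),
                   ifelse(net > 0, "anterograde", "retrograde"))
      expect_equal(lab$net_axial_um, net)
    } else {
      expect_equal(as.character(lab$label), "stationary")
    }
  }
})

test_that("small net displacement is stationary despite a qualifying run", {
  st <- make_steps(rep(2, 20), dir = 1)
  st$axial_delta_um <- rep(c(1, -1), 10) * 0.08
  expect_equal(as.character(classify_motility(st, cfg)$label), "stationary")
})

test_that("directional counts count organelles once per subdomain", {
  crossing <- make_steps(rep(2, 50), s_start = -30, dir = 1,
                         track_id = "cross")
  confined <- make_steps(rep(2, 12), s_start = 10, dir = 1,
                         track_id = "confined")
  st <- assign_bins(dplyr::bind_rows(crossing, confined), cfg)
  labels <- classify_motility(st, cfg)
  counts <- count_directional_movements(st, labels)
  ant <- dplyr::filter(counts, direction == "anterograde")
  expect_equal(ant$n_organelles[ant$subdomain == "proximal"], 1L)
  expect_equal(ant$n_organelles[ant$subdomain == "center"], 1L)
  expect_equal(ant$n_organelles[ant$subdomain == "distal"], 2L)
  expect_true(all(dplyr::filter(counts,
                                direction == "retrograde")$n_organelles == 0))
})

test_that("directional counts match a brute-force per-track scan", {
  set.seed(22)
  st <- dplyr::bind_rows(lapply(1:100, function(i) {
    n <- sample(15:40, 1)
    make_steps(ifelse(runif(n) < 0.15, 0.05, runif(n, 0.5, 2.5)),
               s_start = runif(1, -45, 45),
               dir = sample(c(-1, 1), 1), track_id = sprintf("t%03d", i))
  }))
  st <- assign_bins(st, cfg)
  labels <- classify_motility(st, cfg)
  counts <- count_directional_movements(st, labels)
  # oracle: exhaustive scan over tracks and subdomains
  for (dom in c("proximal", "center", "distal")) {
    for (dir in c("anterograde", "retrograde")) {
      ids <- labels$track_id[labels$label == dir]
      manual <- sum(vapply(ids, function(id) {
        any(st$track_id == id & !st$is_pause &
              as.character(st$subdomain) == dom)
      }, logical(1)))
      got <- counts$n_organelles[counts$subdomain == dom &
                                   counts$direction == dir]
      expect_equal(got, as.integer(manual))
    }
  }
})

test_that("flux normalizes counts to video minutes and pools by direction", {
  counts <- tibble::tibble(
    animal_id = "m1", axon_id = "a1",
    subdomain = factor(rep(c("proximal", "center", "distal"), 2)),
    direction = rep(c("anterograde", "retrograde"), each = 3),
    n_organelles = c(6L, 6L, 6L, 0L, 0L, 0L),
    video_duration_s = 120)
  fl <- flux_per_minute(counts)
  expect_equal(fl$flux_per_min, c(3, 3, 3, 0, 0, 0))
  pooled <- pool_flux(fl)
  expect_equal(pooled$flux_per_min[pooled$direction == "anterograde"], 3)
  expect_equal(pooled$flux_per_min[pooled$direction == "retrograde"], 0)
  # linear in count, inverse in duration
  fl2 <- flux_per_minute(dplyr::mutate(counts, n_organelles = n_organelles * 3L),
                         video_duration_s = 240)
  expect_equal(fl2$flux_per_min, fl$flux_per_min * 3 / 2)
  expect_error(flux_per_minute(counts, video_duration_s = 0),
               class = "nodetrans_validation_error")
})

test_that("direction fractions tally motile labels and sum to one", {
  labels <- tibble::tibble(
    animal_id = "m1", axon_id = "a1", track_id = paste0("t", 1:5),
    label = factor(c("anterograde", "anterograde", "anterograde",
                     "retrograde", "stationary"),
                   levels = c("anterograde", "retrograde", "stationary")))
  fr <- direction_fraction(labels)
  expect_equal(fr$fraction, c(0.75, 0.25))
  expect_equal(sum(fr$fraction), 1)
  all_ant <- dplyr::filter(labels, label == "anterograde")
  expect_equal(direction_fraction(all_ant)$fraction, c(1, 0))
  all_stat <- dplyr::filter(labels, label == "stationary")
  expect_error(direction_fraction(all_stat),
               class = "nodetrans_validation_error")
})

test_that("length summary averages by motility class and region", {
  mk <- function(id, s0, dir, speeds, len) {
    st <- make_steps(speeds, s_start = s0, dir = dir, track_id = id)
    st$length_um <- len
    st
  }
  st <- dplyr::bind_rows(
    mk("s1", -20, 1, rep(0.05, 12), 2), mk("s2", -21, 1, rep(0.05, 12), 2),
    mk("s3", 10, 1, rep(0.05, 12), 2),
    mk("a1", 8, 1, rep(1, 12), 1), mk("a2", -30, 1, rep(1, 12), 1))
  st <- assign_bins(st, cfg)
  labels <- classify_motility(st, cfg)
  ls <- length_summary(st, labels)
  stat <- dplyr::filter(ls, label == "stationary")
  expect_equal(sort(stat$mean_length_um), c(2, 2))
  ant <- dplyr::filter(ls, label == "anterograde")
  expect_equal(unique(ant$mean_length_um), 1)
  # missing lengths drop the class with a warning
  st$length_um[st$track_id == "a1"] <- NA
  st$length_um[st$track_id == "a2"] <- NA
  expect_warning(ls2 <- length_summary(st, labels), "anterograde")
  expect_false("anterograde" %in% as.character(ls2$label))
})

test_that("flipping the distal sign swaps direction labels exactly", {
  sim <- simulate_tracks(generator_config("mito_paper", seed = 3,
                                          n_tracks = 60L, n_stationary = 5L,
                                          n_frames = 80L))
  geom_flip <- axon_geometry(sim$geometry$centerline,
                             sim$geometry$node_center_arclength,
                             distal_sign = -1)
  run <- function(geom) {
    st <- assign_bins(trim_terminal_pauses(
      compute_steps(project_to_axis(sim$tracks, geom), cfg), cfg), cfg)
    classify_motility(st, cfg)
  }
  l1 <- run(sim$geometry)
  l2 <- run(geom_flip)
  j <- dplyr::inner_join(l1, l2, by = "track_id")
  swap <- c(anterograde = "retrograde", retrograde = "anterograde",
            stationary = "stationary")
  expect_equal(unname(swap[as.character(j$label.x)]),
               as.character(j$label.y))
  expect_equal(j$net_axial_um.x, -j$net_axial_um.y)
})
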