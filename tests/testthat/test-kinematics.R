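cfg <- analysis_config()

test_that("step records reproduce the pause definition and gap handling", {
  geom <- straight_geometry()
  # spots 0.04 um apart at dt 0.5 -> 0.08 um/s, a pause
  slow <- make_track("t1", n = 3, step = 0.04, dt = 0.5, x0 = 50)
  st <- compute_steps(project_to_axis(slow, geom), cfg)
  expect_equal(st$speed_um_s, c(0.08, 0.08))
  expect_true(all(st$is_pause))

  # straight run, 1 um per 0.5 s -> every speed 2.0, no pauses
  fast <- make_track("t2", n = 11, step = 1, dt = 0.5, x0 = 30)
  st2 <- compute_steps(project_to_axis(fast, geom), cfg)
  expect_equal(st2$speed_um_s, rep(2, 10))
  expect_false(any(st2$is_pause))
  expect_equal(st2$s_mid_um, seq(-19.5, -10.5, by = 1))

  # frame 3 missing: one spanning record with true elapsed dt, flagged
  gap <- make_track("t3", n = 5, step = 1, dt = 1, x0 = 40)[-4, ]
  st3 <- compute_steps(project_to_axis(gap, geom), cfg)
  expect_equal(nrow(st3), 3)
  expect_equal(st3$dt_s, c(1, 1, 2))
  expect_equal(st3$speed_um_s, c(1, 1, 1))
  expect_equal(st3$is_gap, c(FALSE, FALSE, TRUE))
})

test_that("gaps longer than max_gap_frames split the track", {
  geom <- straight_geometry()
  tr <- make_track("t1", n = 10, step = 1, dt = 1, x0 = 30)
  tr <- tr[tr$frame %in% c(0:3, 7:9), ]  # gap of 4 frames
  st <- compute_steps(project_to_axis(tr, geom), cfg)
  expect_setequal(unique(st$track_id), c("t1", "t1#2"))
  expect_equal(sum(st$track_id == "t1"), 3)
  expect_equal(sum(st$track_id == "t1#2"), 2)
})

test_that("non-positive dt is rejected", {
  tr <- make_track("t1", n = 3)
  tr$t_s <- c(0, 0.5, 0.5)
  tr$s_um <- 0
  expect_error(compute_steps(tr, cfg), class = "nodetrans_validation_error")
})

test_that("terminal pause trimming removes only qualifying terminal runs", {
  mk <- function(pauses_at_end, n = 30) {
    make_steps(c(rep(2, n - pauses_at_end), rep(0.05, pauses_at_end)))
  }
  expect_equal(nrow(trim_terminal_pauses(mk(12), cfg)), 18)
  expect_equal(nrow(trim_terminal_pauses(mk(9), cfg)), 30)
  all_paused <- make_steps(rep(0.05, 12))
  expect_equal(nrow(trim_terminal_pauses(all_paused, cfg)), 0)
  # leading run trimmed too
  lead <- make_steps(c(rep(0.05, 11), rep(2, 10)))
  expect_equal(nrow(trim_terminal_pauses(lead, cfg)), 10)
})

test_that("trimming is idempotent", {
  set.seed(7)
  for (i in 1:10) {
    sp <- ifelse(runif(40) < 0.4, 0.05, 2)
    st <- make_steps(sp)
    once <- trim_terminal_pauses(st, cfg)
    twice <- trim_terminal_pauses(once, cfg)
    expect_equal(twice, once)
  }
})

test_that("qualification requires a 10-step moving run", {
  ok <- make_steps(rep(2, 10))
  expect_true(qualify_tracks(ok, cfg)$accepted)
  # alternating movement never builds a long run
  alt <- make_steps(rep(c(2, 2, 2, 2, 2, 0.05), 5))
  q <- qualify_tracks(alt, cfg)
  expect_false(q$accepted)
  expect_equal(q$reason, "no_qualifying_run")
  expect_equal(q$max_moving_run, 5)
  # empty after trimming
  empty <- trim_terminal_pauses(make_steps(rep(0.05, 15)), cfg)
  expect_equal(nrow(filter_qualified(empty, cfg)), 0)
})

test_that("axon count check applies the 20 / 10-retro-mito thresholds", {
  mk <- function(n, org, dir, axon) {
    tibble::tibble(animal_id = "m1", axon_id = axon,
                   track_id = paste0(axon, dir, seq_len(n)),
                   organelle = org, direction = dir)
  }
  q <- dplyr::bind_rows(
    mk(20, "endosome", "retrograde", "a1"),
    mk(10, "mitochondrion", "retrograde", "a2"),
    mk(19, "endosome", "retrograde", "a3"))
  expect_warning(res <- check_axon_counts(q, cfg), "1 axon group")
  expect_equal(res$status[res$axon_id == "a1"], "pass")
  expect_equal(res$status[res$axon_id == "a2"], "pass")
  expect_equal(res$status[res$axon_id == "a3"], "warn")
  expect_true(all(res$keep))
  res2 <- suppressWarnings(check_axon_counts(q, cfg, exclude = TRUE))
  expect_false(res2$keep[res2$axon_id == "a3"])
})

test_that("bins and subdomains follow the 38/4/38 partition", {
  st <- make_steps(rep(2, 4))
  st$s_mid_um <- c(-39, 0, 2.5, 41)
  b <- assign_bins(st, cfg)
  expect_equal(b$bin_index, c(0L, 20L, 21L, NA))
  expect_equal(as.character(b$subdomain),
               c("proximal", "center", "distal", "outside"))
  # boundary steps at exactly +/-2 go to the node
  st2 <- make_steps(rep(2, 2))
  st2$s_mid_um <- c(-2, 2)
  expect_equal(as.character(assign_bins(st2, cfg)$subdomain),
               c("center", "center"))
})

test_that("summaries compute moving velocity and pause frequency by hand", {
  st <- make_steps(c(rep(0.05, 3), rep(2, 7)))
  st$s_mid_um <- rep(1, 10)  # all in the node bin
  b <- assign_bins(st, cfg)
  sm <- summarize_kinematics(b, cfg)
  expect_equal(nrow(sm), 1)
  expect_equal(sm$pause_relative_frequency, 0.3)
  expect_equal(sm$mean_moving_velocity, 2)
  # a location with only pauses reports a missing velocity
  st2 <- make_steps(rep(0.05, 4))
  st2$s_mid_um <- rep(-10, 4)
  sm2 <- summarize_kinematics(assign_bins(st2, cfg), cfg)
  expect_equal(sm2$pause_relative_frequency, 1)
  expect_true(is.na(sm2$mean_moving_velocity))
})

test_that("pause + moving counts conserve the step total in any grouping", {
  set.seed(11)
  st <- dplyr::bind_rows(lapply(1:8, function(i) {
    make_steps(ifelse(runif(50) < 0.3, 0.05, 2), s_start = runif(1, -45, 25),
               track_id = paste0("t", i), axon_id = paste0("a", i %% 3))
  }))
  b <- assign_bins(st, cfg)
  for (by in c("subdomain", "bin")) {
    sm <- summarize_kinematics(b, cfg, by = by)
    expect_equal(sum(sm$n_steps), sum(b$subdomain != "outside"))
    expect_true(all(sm$n_pauses <= sm$n_steps))
    moving <- sm$n_steps - sm$n_pauses
    expect_equal(sum(moving) + sum(sm$n_pauses), sum(sm$n_steps))
  }
})

test_that("raising the pause threshold never lowers pause frequency", {
  set.seed(12)
  st <- make_steps(runif(200, 0, 3), s_start = -40)
  b <- assign_bins(st, cfg)
  f <- function(thr) {
    b2 <- b
    b2$is_pause <- b2$speed_um_s <= thr
    summarize_kinematics(b2, cfg, by = "bin")
  }
  lo <- f(0.1)
  hi <- f(0.5)
  j <- dplyr::inner_join(lo, hi, by = "bin_index")
  expect_true(all(j$pause_relative_frequency.y >=
                    j$pause_relative_frequency.x))
})

test_that("results do not depend on track order", {
  set.seed(13)
  st <- dplyr::bind_rows(lapply(1:6, function(i) {
    make_steps(ifelse(runif(30) < 0.2, 0.05, runif(30, 1, 3)),
               s_start = runif(1, -40, 20), track_id = paste0("t", i))
  }))
  b <- assign_bins(st, cfg)
  shuffled <- b[sample(nrow(b)), ]
  expect_equal(summarize_kinematics(b, cfg),
               summarize_kinematics(shuffled, cfg))
})

test_that("Pearson correlation matches the direct formula", {
  df <- tibble::tibble(x = c(1, 2, 3, 4), y = c(2, 1, 3, 5))
  res <- pearson_speed_diameter(df, x, y)
  # independent computation from covariance and variances
  r_hand <- sum((df$x - mean(df$x)) * (df$y - mean(df$y))) /
    sqrt(sum((df$x - mean(df$x))^2) * sum((df$y - mean(df$y))^2))
  t_hand <- r_hand * sqrt((4 - 2) / (1 - r_hand^2))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 2)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$p_value, p_hand, tolerance = 1e-12)

  lin <- tibble::tibble(x = 1:5, y = 2 * (1:5) + 3)
  expect_equal(pearson_speed_diameter(lin, x, y)$r, 1)

  expect_error(pearson_speed_diameter(df[1:2, ], x, y),
               class = "nodetrans_validation_error")
  expect_error(pearson_speed_diameter(tibble::tibble(x = c(1, 1, 1),
                                                     y = 1:3), x, y),
               class = "nodetrans_validation_error")
})
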