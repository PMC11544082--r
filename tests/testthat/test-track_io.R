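test_that("track CSV writes and reads back field-for-field", {
  tr <- dplyr::bind_rows(
    make_track("t1", n = 2),
    make_track("t2", n = 5, step = 0.5, y = 1)
  )
  tr$intensity <- seq_len(nrow(tr))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(tr, path)
  back <- read_tracks_csv(path)
  expect_equal(nrow(back), nrow(tr))
  ord <- c("axon_id", "track_id", "frame")
  expect_equal(dplyr::arrange(back, dplyr::across(dplyr::all_of(ord)))[
    , sort(names(tr))],
    dplyr::arrange(tr, dplyr::across(dplyr::all_of(ord)))[, sort(names(tr))])
})

test_that("a 2-row file yields one track with two spots", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("axon_id,track_id,frame,t_s,x_um,y_um,organelle",
               "a1,t1,0,0.0,1.0,2.0,endosome",
               "a1,t1,1,0.5,1.5,2.0,endosome"), path)
  tr <- read_tracks_csv(path)
  expect_equal(nrow(tr), 2)
  expect_equal(unique(tr$track_id), "t1")
})

test_that("malformed tables are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("axon_id,track_id,frame,t_s,x_um,organelle",
               "a1,t1,0,0.0,1.0,endosome"), path)
  expect_error(read_tracks_csv(path), "y_um", class = "nodetrans_format_error")

  dup <- dplyr::bind_rows(make_track("t1", n = 3),
                          make_track("t1", n = 3))
  p2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dup, p2)
  expect_error(read_tracks_csv(p2), "duplicated",
               class = "nodetrans_validation_error")

  bad_t <- make_track("t1", n = 3)
  bad_t$t_s <- c(0, 1, 1)
  p3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad_t, p3)
  expect_error(read_tracks_csv(p3), "monotone",
               class = "nodetrans_validation_error")

  nan_t <- make_track("t1", n = 3)
  nan_t$x_um[2] <- NaN
  expect_error(write_tracks_csv(nan_t, withr::local_tempfile()),
               class = "nodetrans_validation_error")
})

test_that("an empty dataset writes a header-only file", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(make_track(n = 2)[0, ], path)
  expect_equal(length(readLines(path)), 1)
})

test_that("TrackMate XML fixture reads and matches the tabular reader", {
  xml <- read_trackmate_xml(test_path("fixtures", "trackmate_minimal.xml"))
  expect_equal(dplyr::n_distinct(xml$track_id), 1)
  expect_equal(nrow(xml), 3)

  # the same dataset through both readers must be identical
  tr <- make_track("0", n = 4, step = 2, x0 = 10, dt = 1)
  spots <- tibble::tibble(spot_id = as.character(100 + tr$frame),
                          frame = tr$frame, t_s = tr$t_s,
                          x = tr$x_um, y = tr$y_um)
  edges <- data.frame(from = spots$spot_id[-4], to = spots$spot_id[-1])
  xml_path <- withr::local_tempfile(fileext = ".xml")
  writeLines(trackmate_xml_string(spots, list("0" = edges)), xml_path)
  from_xml <- read_trackmate_xml(xml_path, axon_id = "a1", animal_id = "m1")
  common <- c("axon_id", "track_id", "frame", "t_s", "x_um", "y_um", "organelle")
  expect_equal(from_xml[common], tr[common])
})

test_that("TrackMate units are converted and unknown units rejected", {
  tr <- make_track("0", n = 3, step = 1, x0 = 2, dt = 1)
  spots <- tibble::tibble(spot_id = as.character(1:3), frame = tr$frame,
                          t_s = tr$t_s, x = tr$x_um, y = tr$y_um)
  edges <- data.frame(from = spots$spot_id[-3], to = spots$spot_id[-1])
  p_mm <- withr::local_tempfile(fileext = ".xml")
  writeLines(trackmate_xml_string(spots, list("0" = edges), units = "mm"), p_mm)
  expect_equal(read_trackmate_xml(p_mm)$x_um, tr$x_um * 1000)

  p_px <- withr::local_tempfile(fileext = ".xml")
  writeLines(trackmate_xml_string(spots, list("0" = edges), units = "pixel"),
             p_px)
  expect_error(read_trackmate_xml(p_px), "spatial units",
               class = "nodetrans_format_error")
})

test_that("orphan spots are dropped with a warning; dangling edges error", {
  tr <- make_track("0", n = 3, dt = 1)
  spots <- tibble::tibble(spot_id = as.character(1:4),
                          frame = c(tr$frame, 9), t_s = c(tr$t_s, 9),
                          x = c(tr$x_um, 0), y = c(tr$y_um, 0))
  edges <- data.frame(from = c("1", "2"), to = c("2", "3"))
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines(trackmate_xml_string(spots, list("0" = edges)), p)
  expect_warning(out <- read_trackmate_xml(p), "1 spot")
  expect_equal(nrow(out), 3)

  edges_bad <- data.frame(from = c("1", "2"), to = c("2", "99"))
  p2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(trackmate_xml_string(spots[1:3, ], list("0" = edges_bad)), p2)
  expect_error(read_trackmate_xml(p2), "99", class = "nodetrans_format_error")
})

test_that("axis-aligned projection gives exact signed coordinates", {
  geom <- straight_geometry()
  spot <- tibble::tibble(animal_id = "m1", axon_id = "a1", track_id = "t1",
                         frame = 0:1, t_s = c(0, 0.5),
                         x_um = c(60, 50), y_um = c(1, 0),
                         organelle = "endosome")
  pr <- project_to_axis(spot, geom)
  expect_equal(pr$s_um, c(10, 0))
  expect_equal(pr$lateral_um, c(1, 0))
})

test_that("projection matches a dense-sampling oracle on bent polylines", {
  set.seed(42)
  for (rep in 1:5) {
    centerline <- cbind(cumsum(c(0, runif(3, 5, 30))),
                        cumsum(c(0, runif(3, -10, 10))))
    total <- sum(sqrt(rowSums(diff(centerline)^2)))
    node_arc <- total / 2
    geom <- axon_geometry(centerline, node_arc, distal_sign = 1)
    pts <- cbind(runif(20, min(centerline[, 1]), max(centerline[, 1])),
                 runif(20, min(centerline[, 2]) - 5, max(centerline[, 2]) + 5))
    spots <- tibble::tibble(animal_id = "m1", axon_id = "a1", track_id = "t1",
                            frame = seq_len(nrow(pts)) - 1,
                            t_s = (seq_len(nrow(pts)) - 1) * 0.5,
                            x_um = pts[, 1], y_um = pts[, 2],
                            organelle = "endosome")
    pr <- suppressWarnings(project_to_axis(spots, geom, max_lateral_um = Inf))
    for (i in seq_len(nrow(pr))) {
      orc <- oracle_project(c(pr$x_um[i], pr$y_um[i]), centerline, node_arc, 1)
      expect_lt(abs(pr$s_um[i] - orc$s), 0.01)
      expect_lt(abs(pr$lateral_um[i] - orc$lateral), 0.01)
    }
  }
})

test_that("flipping distal_sign negates s exactly", {
  centerline <- rbind(c(0, 0), c(30, 10), c(60, 0))
  g1 <- axon_geometry(centerline, 20, distal_sign = 1)
  g2 <- axon_geometry(centerline, 20, distal_sign = -1)
  spots <- make_track("t1", n = 6, step = 7, x0 = 5, y = 2)
  expect_equal(project_to_axis(spots, g1)$s_um,
               -project_to_axis(spots, g2)$s_um)
})

test_that("spots beyond the lateral cutoff are excluded with a warning", {
  geom <- straight_geometry()
  spots <- make_track("t1", n = 3, y = 0)
  spots$y_um[2] <- 50
  expect_warning(pr <- project_to_axis(spots, geom), "excluded 1")
  expect_equal(nrow(pr), 2)
})
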