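# Shared in-code fixtures: tiny spot tables, geometries and step builders.

straight_geometry <- function(length = 100, node = length / 2, sign = 1) {
  axon_geometry(rbind(c(0, 0), c(length, 0)),
                node_center_arclength = node, distal_sign = sign)
}

# one track moving along +x at constant speed (um per frame), axis-aligned
make_track <- function(track_id = "t1", n = 11, step = 1, dt = 0.5,
                       x0 = 40, y = 0, organelle = "endosome",
                       axon_id = "a1", animal_id = "m1") {
  tibble::tibble(
    animal_id = animal_id, axon_id = axon_id, track_id = track_id,
    frame = 0:(n - 1), t_s = (0:(n - 1)) * dt,
    x_um = x0 + (0:(n - 1)) * step, y_um = y, organelle = organelle
  )
}

# build a step tibble directly from a speed sequence (dt = 0.5 s), with
# axial displacement equal to dir * speed * dt and midpoints at s_mid
make_steps <- function(speeds, dt = 0.5, s_start = 0, dir = 1,
                       track_id = "t1", axon_id = "a1", animal_id = "m1",
                       cfg = analysis_config()) {
  n <- length(speeds)
  deltas <- dir * speeds * dt
  s <- s_start + c(0, cumsum(deltas))
  tibble::tibble(
    animal_id = animal_id, axon_id = axon_id, track_id = track_id,
    frame_from = 0:(n - 1), frame_to = 1:n, dt_s = dt,
    displacement_um = abs(deltas), axial_delta_um = deltas,
    s_mid_um = (s[-(n + 1)] + s[-1]) / 2,
    speed_um_s = speeds, is_gap = FALSE,
    is_pause = speeds <= cfg$pause_speed_threshold
  )
}

# brute-force projection oracle: densely sample the polyline arclength
oracle_project <- function(pt, centerline, node_arc, sign, n_samples = 1e5) {
  seg <- diff(centerline)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  total <- sum(seg_len)
  arc <- seq(0, total, length.out = n_samples)
  idx <- findInterval(arc, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(seg))
  frac <- (arc - cum[idx]) / seg_len[idx]
  px <- centerline[idx, 1] + frac * seg[idx, 1]
  py <- centerline[idx, 2] + frac * seg[idx, 2]
  d2 <- (px - pt[1])^2 + (py - pt[2])^2
  i <- which.min(d2)
  list(s = sign * (arc[i] - node_arc), lateral = sqrt(d2[i]))
}

trackmate_xml_string <- function(spots, tracks, units = "micron") {
  # spots: tibble(spot_id, frame, t_s, x, y); tracks: list(track_id -> edge df)
  spot_lines <- split(spots, spots$frame)
  spots_xml <- paste0(vapply(names(spot_lines), function(fr) {
    rows <- spot_lines[[fr]]
    paste0('  <SpotsInFrame frame="', fr, '">\n',
           paste0('   <Spot ID="', rows$spot_id, '" FRAME="', rows$frame,
                  '" POSITION_T="', rows$t_s, '" POSITION_X="', rows$x,
                  '" POSITION_Y="', rows$y, '" QUALITY="1"/>',
                  collapse = "\n"),
           "\n  </SpotsInFrame>")
  }, character(1)), collapse = "\n")
  tracks_xml <- paste0(vapply(names(tracks), function(tid) {
    e <- tracks[[tid]]
    paste0('  <Track TRACK_ID="', tid, '" name="Track_', tid, '">\n',
           paste0('   <Edge SPOT_SOURCE_ID="', e$from, '" SPOT_TARGET_ID="',
                  e$to, '"/>', collapse = "\n"),
           "\n  </Track>")
  }, character(1)), collapse = "\n")
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         '<TrackMate version="7.0.0">\n',
         ' <Model spatialunits="', units, '" timeunits="sec">\n',
         ' <AllSpots nspots="', nrow(spots), '">\n', spots_xml,
         '\n </AllSpots>\n <AllTracks>\n', tracks_xml,
         '\n </AllTracks>\n </Model>\n</TrackMate>\n')
}
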