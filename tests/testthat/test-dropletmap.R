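# Draw uniform disks (value `fg`) on background `bg` at 0-based centres.
disk_frame <- function(nrow, ncol, x, y, radius, fg = 20000, bg = 3000) {
  m <- matrix(bg, nrow, ncol)
  for (k in seq_along(x)) {
    px <- acidrop:::disc_indices(x[k], y[k], radius[min(k, length(radius))],
                                 nrow, ncol)
    m[px] <- fg
  }
  m
}

test_that("droplet mask segmentation counts disks and filters specks", {
  # blank frame: zero labels, with a warning
  expect_warning(m0 <- build_droplet_mask(matrix(100, 64, 64), 30),
                 "no droplets")
  expect_equal(max(m0), 0)

  # 10 disks plus 5 small specks (10% of droplet area): only disks survive
  centres <- expand.grid(x = c(40, 100, 160, 220, 280), y = c(40, 110))
  speck_r <- sqrt(0.10) * 15  # 10% of the disk area
  fr <- disk_frame(150, 320, centres$x, centres$y, 15)
  for (sx in c(20, 60, 140, 200, 260))
    fr[acidrop:::disc_indices(sx, 140, speck_r, 150, 320)] <- 20000
  mask <- build_droplet_mask(fr, 30)
  expect_equal(max(mask), 10)
})

test_that("well indexing covers the grid and reports missing slots", {
  acq <- small_acq()
  pitch <- acq$well_pitch_px
  g <- expand.grid(col = 0:4, row = 0:4)
  cx <- (g$col + 0.5) * pitch; cy <- (g$row + 0.5) * pitch
  fr <- disk_frame(acq$height, acq$width, cx, cy, 30)
  mask <- build_droplet_mask(fr, 60)
  rec <- index_wells(mask, 5, 5)
  expect_equal(nrow(rec), 25)
  expect_setequal(paste(rec$row, rec$col), paste(g$row, g$col))
  expect_false(any(rec$border_flag))

  # one missing droplet: 24 records and the absent slot reported
  drop <- !(g$row == 2 & g$col == 3)
  fr2 <- disk_frame(acq$height, acq$width, cx[drop], cy[drop], 30)
  mask2 <- build_droplet_mask(fr2, 60)
  expect_message(rec2 <- index_wells(mask2, 5, 5), "1 grid slot")
  expect_equal(nrow(rec2), 24)
  miss <- attr(rec2, "missing_slots")
  expect_equal(unname(unlist(miss)), c(2, 3))

  # more components than slots is an error naming the position
  expect_error(index_wells(mask, 2, 2, position = 77), "position 77")
})

test_that("indexing with jitter matches the nearest-grid-point oracle", {
  acq <- small_acq()
  pitch <- acq$well_pitch_px
  set.seed(12)
  g <- expand.grid(col = 0:4, row = 0:4)
  cx <- (g$col + 0.5) * pitch + runif(25, -2, 2)
  cy <- (g$row + 0.5) * pitch + runif(25, -2, 2)
  fr <- disk_frame(acq$height, acq$width, cx, cy, 30)
  mask <- build_droplet_mask(fr, 60)
  rec <- index_wells(mask, 5, 5)
  # oracle: nearest ideal grid point for each recovered centroid
  for (i in seq_len(nrow(rec))) {
    d <- (cx - rec$x[i])^2 + (cy - rec$y[i])^2
    j <- which.min(d)
    expect_equal(rec$row[i], g$row[j])
    expect_equal(rec$col[i], g$col[j])
  }
})

test_that("indexing is stable across frames for immobilized droplets", {
  acq <- small_acq(duration_min = 20)
  p <- synth_params(seed = 14, lambda_cells = 1)
  rp <- acidrop:::render_position(p, acq, 1)
  recs <- lapply(rp$stacks$CY5_667, function(fr) {
    mask <- build_droplet_mask(fr, acq$droplet_diameter_px)
    index_wells(mask, 5, 5)
  })
  ref <- recs[[1]][, c("row", "col", "x", "y")]
  agree <- vapply(recs[-1], function(r) {
    m <- merge(ref, r[, c("row", "col", "x", "y")], by = c("row", "col"))
    mean(sqrt((m$x.x - m$x.y)^2 + (m$y.x - m$y.y)^2) < 2)
  }, 0)
  expect_gte(min(agree), 0.99)
})

test_that("central-area rule assigns by median track position", {
  rec <- data.frame(position = 1, row = 0, col = 0, x = 100, y = 100,
                    radius = 30, label = 1, border_flag = FALSE)
  mk_track <- function(id, x, y, channel = "GREEN", nf = 10)
    data.frame(track_id = id, frame = 1:nf, x = x, y = y, m0 = 1, m2 = 1,
               intensity = 1, channel = channel)
  # track at the droplet centre is counted
  r1 <- assign_cells(mk_track(1, 100, 100), rec)
  expect_equal(r1$n_green, 1)
  # track at 0.9 R is outside the central 60% area (0.9 > sqrt(0.6))
  r2 <- assign_cells(mk_track(1, 100 + 0.9 * 30, 100), rec)
  expect_equal(r2$n_green, 0)
  expect_equal(unname(attr(r2, "diagnostics")["annulus"]), 1L)
  # short tracks are ignored
  r3 <- assign_cells(mk_track(1, 100, 100, nf = 3), rec)
  expect_equal(r3$n_green, 0)
  # radius-fraction alternative accepts 0.59 R under rule = "radius"
  r4 <- assign_cells(mk_track(1, 100 + 0.59 * 30, 100), rec, rule = "radius")
  expect_equal(r4$n_green, 1)
})

test_that("uniformly scattered tracks are kept in proportion to the area rule", {
  rec <- data.frame(position = 1, row = 0, col = 0, x = 200, y = 200,
                    radius = 100, label = 1, border_flag = FALSE)
  set.seed(31)
  n <- 4000
  # uniform points in the droplet disk
  rr <- 100 * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  tracks <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(track_id = i, frame = 1:5, x = 200 + rr[i] * cos(th[i]),
               y = 200 + rr[i] * sin(th[i]), m0 = 1, m2 = 1, intensity = 1,
               channel = "GREEN")))
  r <- assign_cells(tracks, rec)
  dg <- attr(r, "diagnostics")
  frac <- dg[["assigned"]] / n
  expect_lt(abs(frac - 0.6), 3 * sqrt(0.6 * 0.4 / n) + 0.01)
})

test_that("occupancy classification reconciles the two label channels", {
  cls <- classify_occupancy(c(0, 0, 1, 1, 0, 2), c(0, 1, 0, 2, 3, 1))
  expect_equal(cls$class,
               c("EMPTY", "SINGLE", "SINGLE", "MULTI", "MULTI", "MULTI"))
  expect_equal(cls$emulsion, c("NONE", "UT", "HG", "UT", "UT", "HG"))
  expect_equal(cls$mixed_flag, c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_error(classify_occupancy(-1, 0), "non-negative")
  expect_error(classify_occupancy(c(1, 2), 0), "same length")
})

test_that("classification accuracy reaches 0.95 on noiseless data at low lambda", {
  acq <- small_acq()
  p <- synth_params(seed = 19, lambda_cells = 0.5, noise_sigma = 0)
  out <- run_small_pipeline(p, acq)
  m <- out$merged
  truth_cls <- ifelse(m$n_cells == 0, "EMPTY",
                      ifelse(m$n_cells == 1, "SINGLE", "MULTI"))
  expect_gte(mean(truth_cls == m$class), 0.95)
  # conservation: every indexed droplet lands in exactly one class
  expect_equal(sum(table(m$class)), nrow(m))
})
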