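test_that("image restoration removes background and preserves spot maxima", {
  expect_equal(max(abs(restore_image(matrix(7, 64, 64), 10))), 0,
               tolerance = 1e-10)
  expect_error(restore_image(matrix(0, 16, 16), 10), "radius")

  # single spot on flat background: maximum at the spot centre
  m <- spot_frame(64, 64, x = 40, y = 22, amplitude = 500, sigma = 2,
                  background = 50)
  r <- restore_image(m, 8)
  peak <- which(r == max(r), arr.ind = TRUE)
  expect_lte(abs(peak[1] - 1 - 22), 1)
  expect_lte(abs(peak[2] - 1 - 40), 1)

  # ramp background plus spot: spot remains the global maximum
  ramp <- outer(seq(0, 400, length.out = 64), seq(0, 200, length.out = 64),
                "+")
  m2 <- acidrop:::add_spot(ramp, 30, 25, 300, 2)
  r2 <- restore_image(m2, 8)
  peak2 <- which(r2 == max(r2), arr.ind = TRUE)
  expect_lte(abs(peak2[1] - 1 - 25), 1)
  expect_lte(abs(peak2[2] - 1 - 30), 1)
})

test_that("detection finds isolated spots with sub-pixel accuracy", {
  # the brightness percentile is matched to the expected particle area, as
  # in the real assay; a lone spot in a 96x96 frame occupies ~0.25%
  tp <- tracker_params(radius = 8, percentile = 0.25)
  m <- spot_frame(96, 96, x = 47.3, y = 31.6, amplitude = 1000, sigma = 3,
                  background = 100, noise_sd = 100, seed = 1)
  d <- detect_particles(restore_image(m, tp$radius), tp)
  expect_equal(nrow(d), 1)
  expect_lt(sqrt((d$x - 47.3)^2 + (d$y - 31.6)^2), 0.5)
  expect_gt(d$m0, 0)

  # two spots three radii apart stay separate
  m2 <- spot_frame(96, 96, x = c(30, 30 + 3 * 8), y = c(48, 48),
                   amplitude = 1000, sigma = 3, background = 100)
  d2 <- detect_particles(restore_image(m2, tp$radius), tp)
  expect_equal(nrow(d2), 2)

  # an empty image gives an empty result, not an error
  expect_equal(nrow(detect_particles(matrix(0, 32, 32), tp)), 0)
})

test_that("detection recall and precision reach 0.95 on 50 random spots", {
  tp <- tracker_params(radius = 8, percentile = 1)
  truth <- random_spot_centres(50, 512, 512, min_sep = 3 * 8, margin = 12,
                               seed = 33)
  m <- spot_frame(512, 512, truth$x, truth$y, amplitude = 1200, sigma = 3,
                  background = 200, noise_sd = 120, seed = 34)
  d <- detect_particles(restore_image(m, tp$radius), tp)
  # match detections to truth within the kernel radius
  hits <- vapply(seq_len(nrow(truth)), function(i) {
    any(sqrt((d$x - truth$x[i])^2 + (d$y - truth$y[i])^2) <= 8)
  }, TRUE)
  correct <- vapply(seq_len(nrow(d)), function(j) {
    any(sqrt((d$x[j] - truth$x)^2 + (d$y[j] - truth$y)^2) <= 8)
  }, TRUE)
  expect_gte(mean(hits), 0.95)     # recall
  expect_gte(mean(correct), 0.95)  # precision
})

test_that("detection is translation-equivariant", {
  tp <- tracker_params(radius = 8, percentile = 2)
  truth <- random_spot_centres(5, 128, 128, min_sep = 30, margin = 25,
                               seed = 8)
  m <- spot_frame(128, 128, truth$x, truth$y, amplitude = 900, sigma = 3,
                  background = 80, noise_sd = 50, seed = 9)
  dx <- 3L; dy <- 5L
  shifted <- matrix(80, 128, 128)
  shifted[(1 + dy):128, (1 + dx):128] <- m[1:(128 - dy), 1:(128 - dx)]
  d0 <- detect_particles(restore_image(m, tp$radius), tp)
  d1 <- detect_particles(restore_image(shifted, tp$radius), tp)
  d0 <- d0[order(d0$x), ]; d1 <- d1[order(d1$x), ]
  keep0 <- d0$x < 128 - 1 - dx - 15 & d0$y < 128 - 1 - dy - 15
  d0 <- d0[keep0, ]
  d1 <- d1[d1$x >= min(d0$x + dx) - 1 & d1$y >= min(d0$y + dy) - 1, ]
  expect_equal(nrow(d0), nrow(d1))
  expect_lt(max(abs(d1$x - (d0$x + dx))), 0.1)
  expect_lt(max(abs(d1$y - (d0$y + dy))), 0.1)
})

test_that("discrimination keeps everything at cutoff 0 and nothing at +Inf", {
  d <- data.frame(x = runif(20), y = runif(20),
                  m0 = c(rnorm(10, 10, 0.5), rnorm(10, 30, 0.5)),
                  m2 = c(rnorm(10, 4, 0.2), rnorm(10, 20, 0.2)),
                  intensity = 1)
  expect_equal(nrow(discriminate(d, 0)), 20)
  expect_equal(nrow(discriminate(d, Inf)), 0)
  scored <- discriminate(d, 0)
  expect_equal(nrow(discriminate(d, median(scored$score))), 10)
})

test_that("linking follows moving and stationary spots without swaps", {
  tp <- tracker_params()
  # one spot moving 2 px/frame for 10 frames: a single 10-frame track
  det <- do.call(rbind, lapply(1:10, function(f)
    data.frame(frame = f, x = 10 + 2 * f, y = 20, m0 = 10, m2 = 4)))
  tr <- link_tracks(det, tp)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 10)

  # two stationary spots far apart: two tracks, no identity swap
  det2 <- do.call(rbind, lapply(1:8, function(f)
    data.frame(frame = f, x = c(10, 110), y = c(10, 10), m0 = 10, m2 = 4)))
  tr2 <- link_tracks(det2, tp)
  expect_equal(length(unique(tr2$track_id)), 2)
  for (id in unique(tr2$track_id))
    expect_equal(length(unique(tr2$x[tr2$track_id == id])), 1)

  # a spot disappearing for 2 frames (< link_range) stays one track
  det3 <- data.frame(frame = c(1, 2, 3, 6, 7), x = 50 + c(0, 1, 2, 3, 4),
                     y = 50, m0 = 10, m2 = 4)
  tr3 <- link_tracks(det3, tp)
  expect_equal(length(unique(tr3$track_id)), 1)
  expect_equal(sort(tr3$frame), c(1, 2, 3, 6, 7))
})

test_that("linking equals the brute-force optimal assignment on small instances", {
  tp <- tracker_params()
  set.seed(21)
  for (rep in 1:12) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    d1 <- data.frame(x = runif(n1, 0, 40), y = runif(n1, 0, 40),
                     m0 = runif(n1, 8, 12), m2 = runif(n1, 3, 5))
    d2 <- data.frame(x = d1$x[seq_len(min(n1, n2))] + rnorm(min(n1, n2), 0, 2),
                     y = d1$y[seq_len(min(n1, n2))] + rnorm(min(n1, n2), 0, 2),
                     m0 = runif(min(n1, n2), 8, 12),
                     m2 = runif(min(n1, n2), 3, 5))
    if (n2 > n1) {
      extra <- n2 - n1
      d2 <- rbind(d2, data.frame(x = runif(extra, 0, 40),
                                 y = runif(extra, 0, 40),
                                 m0 = runif(extra, 8, 12),
                                 m2 = runif(extra, 3, 5)))
    }
    oracle <- brute_force_pairing(d1, d2, tp$max_displacement)
    got <- linker_pairing(d1, d2, tp)
    expect_identical(got, oracle$pairing,
                     label = paste("instance", rep))
  }
})

test_that("linking matches greedy nearest-neighbour on well-separated tracks", {
  tp <- tracker_params()
  set.seed(55)
  n <- 8; nf <- 6
  start <- random_spot_centres(n, 400, 400, min_sep = 4 * tp$max_displacement,
                               margin = 30, seed = 56)
  pos <- array(NA_real_, c(n, 2, nf))
  pos[, , 1] <- as.matrix(start)
  for (f in 2:nf) pos[, , f] <- pos[, , f - 1] + rnorm(2 * n, 0, sqrt(2))
  det <- do.call(rbind, lapply(1:nf, function(f)
    data.frame(frame = f, x = pos[, 1, f], y = pos[, 2, f], m0 = 10, m2 = 4)))
  tr <- link_tracks(det, tp)
  expect_equal(length(unique(tr$track_id)), n)
  # greedy nearest-neighbour oracle: each detection joins its nearest
  # predecessor in the previous frame
  for (f in 2:nf) {
    for (k in 1:n) {
      d <- sqrt((pos[, 1, f - 1] - pos[k, 1, f])^2 +
                  (pos[, 2, f - 1] - pos[k, 2, f])^2)
      expect_equal(which.min(d), k)  # construction keeps identities separate
    }
  }
  # conservation: every detection belongs to exactly one track
  expect_equal(nrow(tr), nrow(det))
  key_in <- sort(paste(det$frame, round(det$x, 9), round(det$y, 9)))
  key_out <- sort(paste(tr$frame, round(tr$x, 9), round(tr$y, 9)))
  expect_identical(key_out, key_in)
})

test_that("tracker parameter validation enforces plugin-like bounds", {
  expect_error(tracker_params(radius = 0), "radius")
  expect_error(tracker_params(percentile = 0), "percentile")
  expect_error(tracker_params(link_range = 0), "link_range")
  expect_error(tracker_params(max_displacement = 0), "max_displacement")
  expect_error(tracker_params(dynamics = "Levy"), "Brownian")
})
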