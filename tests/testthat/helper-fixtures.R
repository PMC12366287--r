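# Shared fixtures and independent oracles, all built in code.

# Compact acquisition: 5 x 5 wells, full-size droplets (60 px), 5-min cadence
# over 60 min -> 13 frames. Small enough for per-test pipelines, large enough
# that all default tracker/droplet geometry assumptions hold unchanged.
small_acq <- function(n_positions = 1L, duration_min = 60) {
  acquisition_config(grid_rows = 5L, grid_cols = 5L,
                     n_positions = n_positions, duration_min = duration_min)
}

# A flat-background frame with Gaussian spots at given 0-based (x, y).
spot_frame <- function(nrow, ncol, x, y, amplitude = 1000, sigma = 3,
                       background = 100, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(background, nrow, ncol)
  for (k in seq_along(x))
    m <- acidrop:::add_spot(m, x[k], y[k], amplitude, sigma)
  if (noise_sd > 0) m <- m + matrix(rnorm(length(m), 0, noise_sd), nrow, ncol)
  m
}

# Draw n spot centres with pairwise separation >= min_sep, margin from edges.
random_spot_centres <- function(n, nrow, ncol, min_sep, margin, seed) {
  set.seed(seed)
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    x <- runif(1, margin, ncol - 1 - margin)
    y <- runif(1, margin, nrow - 1 - margin)
    if (length(xs) == 0 || all(sqrt((xs - x)^2 + (ys - y)^2) >= min_sep)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  data.frame(x = xs, y = ys)
}

# Brute-force two-frame linking oracle: enumerates every injective partial
# assignment between frame-1 and frame-2 detections under the same cost model
# as the linker (squared displacement + squared moment differences; leaving a
# detection unlinked costs L^2 on each side; links beyond L are infeasible).
# Returns the optimal pairing as a vector: for each frame-1 index the matched
# frame-2 index or NA. Independent of the package implementation.
brute_force_pairing <- function(d1, d2, L) {
  n1 <- nrow(d1); n2 <- nrow(d2)
  cost <- function(i, j) {
    dd <- (d1$x[i] - d2$x[j])^2 + (d1$y[i] - d2$y[j])^2
    if (sqrt(dd) > L) return(Inf)
    dd + (d1$m0[i] - d2$m0[j])^2 + (d1$m2[i] - d2$m2[j])^2
  }
  best <- list(total = Inf, pairing = rep(NA_integer_, n1))
  recurse <- function(i, used, pairing, total) {
    if (i > n1) {
      total <- total + L^2 * sum(!seq_len(n2) %in% used)  # unborn detections
      if (total < best$total) best <<- list(total = total, pairing = pairing)
      return(invisible())
    }
    recurse(i + 1L, used, pairing, total + L^2)  # leave i unlinked (death)
    for (j in setdiff(seq_len(n2), used)) {
      cc <- cost(i, j)
      if (is.finite(cc)) {
        pairing[i] <- j
        recurse(i + 1L, c(used, j), pairing, total + cc)
        pairing[i] <- NA_integer_
      }
    }
  }
  recurse(1L, integer(0), rep(NA_integer_, n1), 0)
  best
}

# Pairing produced by the package linker on a two-frame instance.
linker_pairing <- function(d1, d2, params) {
  det <- rbind(cbind(frame = 1L, d1), cbind(frame = 2L, d2))
  tr <- link_tracks(det, params)
  pairing <- rep(NA_integer_, nrow(d1))
  for (id in unique(tr$track_id)) {
    seg <- tr[tr$track_id == id, ]
    if (nrow(seg) == 2L) {
      i1 <- which(d1$x == seg$x[seg$frame == 1] &
                    d1$y == seg$y[seg$frame == 1])
      i2 <- which(d2$x == seg$x[seg$frame == 2] &
                    d2$y == seg$y[seg$frame == 2])
      pairing[i1] <- i2
    }
  }
  pairing
}

# Run the full pipeline on a synthetic render held in memory (no TIFF I/O),
# returning classification results merged against truth.
run_small_pipeline <- function(params, acq, position = 1L,
                               tracker = tracker_params(),
                               cal = calibration_model()) {
  rp <- acidrop:::render_position(params, acq, position, cal)
  tracks <- rbind(
    track_stack(rp$stacks$GREEN, tracker, channel = "GREEN"),
    track_stack(rp$stacks$UV, tracker, channel = "UV"))
  rec <- map_droplets(rp$stacks$CY5_667, tracks, acq, position = position)
  q <- quantify_ph(rp$stacks$CY3_600, rp$stacks$CY5_667, rec, cal, acq$times)
  merged <- merge(rp$truth_droplets, q$summary,
                  by = c("position", "row", "col"))
  list(render = rp, tracks = tracks, records = rec, quant = q,
       merged = merged)
}
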