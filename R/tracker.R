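#' Feature-point tracker parameters
#'
#' Parameters of the intensity-moment feature-point tracker used to detect
#' labelled cells in the GREEN/UV channels and link them into trajectories.
#' Defaults follow the established plugin settings for this assay:
#' radius 10 px, percentile 0.6, cutoff 0, link range 4, displacement 5,
#' Brownian dynamics.
#'
#' @param radius detection kernel radius w in pixels.
#' @param percentile brightness percentile (in percent) used to threshold
#'   candidate pixels; the top `percentile` % of restored intensities are
#'   candidates. Ignored when `threshold_mode = "absolute"`.
#' @param cutoff non-particle discrimination score threshold; 0 keeps all.
#' @param link_range number of frames ahead considered when closing gaps.
#' @param max_displacement maximum per-frame movement in pixels.
#' @param dynamics motion model tag; only `"Brownian"` is implemented.
#' @param threshold_mode `"percentile"` (default plugin semantics) or
#'   `"absolute"` (interpret `percentile` as an absolute intensity threshold
#'   on the restored image).
#' @return An object of class `tracker_params`.
#' @export
tracker_params <- function(radius = 10L, percentile = 0.6, cutoff = 0,
                           link_range = 4L, max_displacement = 5,
                           dynamics = "Brownian",
                           threshold_mode = c("percentile", "absolute")) {
  threshold_mode <- match.arg(threshold_mode)
  check_number(radius, "radius", min = 1)
  if (threshold_mode == "percentile")
    check_number(percentile, "percentile", min = 1e-12, max = 100)
  check_number(link_range, "link_range", min = 1)
  check_number(max_displacement, "max_displacement",
               min = .Machine$double.eps)
  if (!identical(dynamics, "Brownian"))
    stop2("only Brownian dynamics is supported")
  structure(list(radius = as.integer(radius), percentile = percentile,
                 cutoff = cutoff, link_range = as.integer(link_range),
                 max_displacement = max_displacement, dynamics = dynamics,
                 threshold_mode = threshold_mode),
            class = "tracker_params")
}

#' Restore (band-pass filter) an image for particle detection
#'
#' Background subtraction and noise suppression in one pass: the image is
#' convolved with a Gaussian of unit width (signal smoothing) and with a
#' boxcar of half-width `radius` (local background estimate), and the two are
#' subtracted. A constant image restores to zeros; large-scale background
#' ramps are removed while spots of size up to ~`radius` are preserved.
#'
#' @param image 2-D numeric matrix.
#' @param radius detection kernel radius in pixels.
#' @return Real-valued matrix of the same size.
#' @export
restore_image <- function(image, radius = 10L) {
  if (!is.matrix(image)) stop2("image must be a 2-D matrix")
  if (radius > min(dim(image)) / 2)
    stop2("radius exceeds half the image size")
  w <- as.integer(radius)
  side <- 2L * w + 1L
  lambda <- 1  # Gaussian correlation length (px)
  g1 <- exp(-((-w:w)^2) / (4 * lambda^2))
  g1 <- g1 / sum(g1)
  b1 <- rep(1 / side, side)
  # both kernels are separable: two 1-D passes each, replicate boundary
  sep_filter(image, g1) - sep_filter(image, b1)
}

# Separable symmetric filtering with replicate boundary handling.
sep_filter <- function(m, k) {
  w <- (length(k) - 1L) %/% 2L
  pad_rows <- function(x) rbind(x[rep(1L, w), , drop = FALSE], x,
                                x[rep(nrow(x), w), , drop = FALSE])
  pass <- function(x) {
    f <- stats::filter(pad_rows(x), k, sides = 2)
    matrix(f[(w + 1L):(nrow(x) + w), ], nrow(x), ncol(x))
  }
  t(pass(t(pass(m))))
}

#' Detect particles in a restored image
#'
#' Finds intensity local maxima within `radius`, keeps those whose restored
#' intensity lies in the upper `percentile` of the frame's intensity
#' distribution, merges detections closer than `radius` (keeping the
#' brighter), and refines each centroid by the intensity-weighted mean over
#' its disc neighbourhood. Intensity moments are computed on the restored
#' image normalized to its frame maximum, so that moment magnitudes are
#' comparable across frames even under photobleaching: `m0` is the summed
#' (normalized) intensity over the disc and `m2` the intensity-weighted mean
#' squared radius.
#'
#' @param image restored image (from [restore_image()]).
#' @param params a [tracker_params()].
#' @param raw optional raw frame; when supplied each detection also carries
#'   `intensity`, the background-subtracted mean raw intensity over the disc
#'   (used downstream for bleaching correction).
#' @return A data.frame with columns `x`, `y` (0-based sub-pixel centroids),
#'   `m0`, `m2`, `intensity`. Empty images yield an empty data.frame.
#' @export
detect_particles <- function(image, params = tracker_params(), raw = NULL) {
  w <- params$radius
  empty <- data.frame(x = numeric(0), y = numeric(0), m0 = numeric(0),
                      m2 = numeric(0), intensity = numeric(0))
  if (length(image) == 0L || all(image == image[1])) return(empty)
  mx <- max(image)

  thr <- if (params$threshold_mode == "percentile")
    stats::quantile(image, 1 - params$percentile / 100, names = FALSE)
  else params$percentile

  brush <- EBImage::makeBrush(2L * w + 1L, shape = "disc")
  dil <- EBImage::dilate(image, brush)
  if (inherits(dil, "Image")) dil <- EBImage::imageData(dil)
  cand <- which(image >= dil & image > thr, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)

  # moment weights are taken above the candidate threshold so that moments
  # describe the particle, not the surrounding background noise
  norm <- pmax(image - thr, 0) / mx
  raw_median <- if (!is.null(raw)) stats::median(raw) else NA_real_
  off <- disc_offsets(w)
  nr <- nrow(image); nc <- ncol(image)
  res <- matrix(NA_real_, nrow(cand), 5)
  for (k in seq_len(nrow(cand))) {
    ci <- cand[k, 1]; cj <- cand[k, 2]
    # iterative intensity-weighted centroid refinement
    for (it in 1:5) {
      ii <- ci + off$di; jj <- cj + off$dj
      keep <- ii >= 1L & ii <= nr & jj >= 1L & jj <= nc
      ii <- ii[keep]; jj <- jj[keep]
      wts <- pmax(norm[cbind(ii, jj)], 0)
      if (sum(wts) <= 0) break
      ei <- sum(wts * ii) / sum(wts) - ci
      ej <- sum(wts * jj) / sum(wts) - cj
      if (abs(ei) < 0.5 && abs(ej) < 0.5) break
      ci <- min(max(ci + round(ei), 1L), nr)
      cj <- min(max(cj + round(ej), 1L), nc)
    }
    ii <- ci + off$di; jj <- cj + off$dj
    keep <- ii >= 1L & ii <= nr & jj >= 1L & jj <= nc
    ii <- ii[keep]; jj <- jj[keep]
    wts <- pmax(norm[cbind(ii, jj)], 0)
    m0 <- sum(wts)
    if (m0 <= 0) next
    yc <- sum(wts * ii) / m0
    xc <- sum(wts * jj) / m0
    m2 <- sum(wts * ((ii - yc)^2 + (jj - xc)^2)) / m0
    inten <- if (!is.null(raw))
      mean(raw[cbind(ii, jj)]) - raw_median else m0
    res[k, ] <- c(xc - 1, yc - 1, m0, m2, inten)  # 0-based output
  }
  res <- res[stats::complete.cases(res), , drop = FALSE]
  if (nrow(res) == 0L) return(empty)

  # merge detections closer than radius, keeping the brighter (larger m0)
  ord <- order(res[, 3], decreasing = TRUE)
  res <- res[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  for (k in seq_len(nrow(res))) {
    if (!keep[k]) next
    if (k < nrow(res)) {
      later <- (k + 1):nrow(res)
      d <- sqrt((res[later, 1] - res[k, 1])^2 + (res[later, 2] - res[k, 2])^2)
      keep[later][d < w] <- FALSE
    }
  }
  res <- res[keep, , drop = FALSE]
  data.frame(x = res[, 1], y = res[, 2], m0 = res[, 3], m2 = res[, 4],
             intensity = res[, 5])
}

#' Non-particle discrimination
#'
#' Scores each detection by the fitted bivariate Gaussian density of the
#' (m0, m2) moment cloud and removes detections scoring below `cutoff`.
#' True particles form a dense cluster in moment space while spurious
#' detections fall in its tails. With the default `cutoff = 0` every
#' detection passes (all densities are positive).
#'
#' @param detections data.frame from [detect_particles()].
#' @param cutoff score threshold; detections with score < cutoff are removed.
#' @return The filtered data.frame; scores are attached as column `score`.
#' @export
discriminate <- function(detections, cutoff = 0) {
  n <- nrow(detections)
  if (n == 0L) return(cbind(detections, score = numeric(0)))
  M <- cbind(detections$m0, detections$m2)
  if (n < 3L) {
    score <- rep(1, n)
  } else {
    mu <- colMeans(M)
    S <- stats::cov(M) + diag(1e-12, 2)
    d2 <- stats::mahalanobis(M, mu, S)
    score <- exp(-d2 / 2) / (2 * pi * sqrt(det(S)))
  }
  out <- cbind(detections, score = score)
  out[score >= cutoff, , drop = FALSE]
}

#' Link per-frame detections into trajectories
#'
#' Frame-to-frame association minimizing the total link cost
#' \eqn{d^2 + \Delta m_0^2 + \Delta m_2^2} by optimal bipartite assignment
#' (solved exactly per frame), subject to a displacement limit of
#' `max_displacement` pixels per frame step. Particles may disappear for up
#' to `link_range - 1` frames and be re-linked (the displacement budget
#' scales with the gap length); the cost of leaving a track or a detection
#' unlinked is `max_displacement^2`. Every detection belongs to exactly one
#' track; unlinkable detections start new tracks.
#'
#' @param detections a data.frame with columns `frame` (1-based integer),
#'   `x`, `y`, `m0`, `m2` and optionally `intensity`, or a list of per-frame
#'   data.frames.
#' @param params a [tracker_params()].
#' @return A data.frame of class `cell_tracks` with columns `track_id`,
#'   `frame`, `x`, `y`, `m0`, `m2`, `intensity`, ordered by track then frame.
#' @export
link_tracks <- function(detections, params = tracker_params()) {
  if (is.list(detections) && !is.data.frame(detections)) {
    detections <- do.call(rbind, lapply(seq_along(detections), function(f) {
      d <- detections[[f]]
      if (nrow(d) == 0L) return(NULL)
      cbind(frame = f, d)
    }))
    if (is.null(detections))
      detections <- data.frame(frame = integer(0), x = numeric(0),
                               y = numeric(0), m0 = numeric(0),
                               m2 = numeric(0))
  }
  if (!all(c("frame", "x", "y") %in% names(detections)))
    stop2("detections need columns frame, x, y")
  if (is.null(detections$m0)) detections$m0 <- 0
  if (is.null(detections$m2)) detections$m2 <- 0
  if (is.null(detections$intensity)) detections$intensity <- detections$m0

  L <- params$max_displacement
  BIG <- 1e12
  frames <- sort(unique(detections$frame))
  tracks <- list()   # each: list(frames=, idx=) indices into detections
  last_frame <- integer(0)

  for (f in frames) {
    rows <- which(detections$frame == f)
    nd <- length(rows)
    active <- which(last_frame >= f - params$link_range & last_frame < f)
    na <- length(active)
    linked_det <- rep(FALSE, nd)
    if (na > 0L && nd > 0L) {
      C <- matrix(BIG, na, nd)
      for (a in seq_len(na)) {
        tr <- tracks[[active[a]]]
        i <- tr$idx[length(tr$idx)]
        gap <- f - last_frame[active[a]]
        dx <- detections$x[rows] - detections$x[i]
        dy <- detections$y[rows] - detections$y[i]
        d2 <- dx^2 + dy^2
        feas <- sqrt(d2) <= L * gap
        cost <- d2 + (detections$m0[rows] - detections$m0[i])^2 +
          (detections$m2[rows] - detections$m2[i])^2
        C[a, feas] <- cost[feas]
      }
      n <- na + nd
      A <- matrix(BIG, n, n)
      A[seq_len(na), seq_len(nd)] <- C
      A[cbind(seq_len(na), nd + seq_len(na))] <- L^2     # track death
      A[cbind(na + seq_len(nd), seq_len(nd))] <- L^2     # detection birth
      A[na + seq_len(nd), nd + seq_len(na)] <- 0         # dummy-dummy
      sol <- clue::solve_LSAP(A)
      for (a in seq_len(na)) {
        j <- sol[a]
        if (j <= nd && C[a, j] < BIG) {
          ti <- active[a]
          tracks[[ti]]$idx <- c(tracks[[ti]]$idx, rows[j])
          last_frame[ti] <- f
          linked_det[j] <- TRUE
        }
      }
    }
    for (j in which(!linked_det)) {
      tracks[[length(tracks) + 1L]] <- list(idx = rows[j])
      last_frame[length(tracks)] <- f
    }
  }

  out <- do.call(rbind, lapply(seq_along(tracks), function(t) {
    idx <- tracks[[t]]$idx
    data.frame(track_id = t, frame = detections$frame[idx],
               x = detections$x[idx], y = detections$y[idx],
               m0 = detections$m0[idx], m2 = detections$m2[idx],
               intensity = detections$intensity[idx])
  }))
  if (is.null(out))
    out <- data.frame(track_id = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0), m0 = numeric(0),
                      m2 = numeric(0), intensity = numeric(0))
  class(out) <- c("cell_tracks", "data.frame")
  out
}

#' Track cells through an image stack
#'
#' Convenience wrapper running restoration, detection, discrimination and
#' linking over every frame of a label-channel stack.
#'
#' @param stack list of frames (numeric matrices) in acquisition order.
#' @param params a [tracker_params()].
#' @param channel optional channel name attached to the output.
#' @return A `cell_tracks` data.frame (see [link_tracks()]) with an added
#'   `channel` column.
#' @export
track_stack <- function(stack, params = tracker_params(), channel = NA) {
  dets <- lapply(stack, function(frame) {
    restored <- restore_image(frame, params$radius)
    d <- detect_particles(restored, params, raw = frame)
    d <- discriminate(d, params$cutoff)
    d[, c("x", "y", "m0", "m2", "intensity")]
  })
  tr <- link_tracks(dets, params)
  tr$channel <- channel
  tr
}
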