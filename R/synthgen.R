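#' Synthetic-experiment parameters
#'
#' Parameters of the ground-truthed synthetic microwell-array generator. The
#' defaults reproduce the study conditions of the two-population encapsulation
#' experiment: Poisson cell loading at \eqn{\lambda = 1.716} (design
#' concentration 1.2e7 cells/mL in 143 pL droplets), a 1:1 mix of
#' hyperglycolytic (HG, green-labelled) and untreated (UT, violet-labelled)
#' droplet emulsions, mean 3-h extracellular pH drops of 0.17 (HG single cell),
#' 0.065 (UT single cell) and 0.021 (empty-droplet drift), and per-cell
#' lognormal rate heterogeneity with CV 0.4 (which reproduces the observed
#' +-0.07 spread around the 0.17 HG single-cell mean).
#'
#' @param lambda_cells mean number of cells per droplet (Poisson rate).
#' @param frac_hg fraction of droplets drawn from the HG emulsion, in [0, 1].
#' @param dph_mean_hg_single mean total 3-h pH drop of a droplet holding one
#'   HG cell (baseline drift included).
#' @param dph_mean_ut_single mean total 3-h pH drop of a droplet holding one
#'   UT cell.
#' @param dph_empty baseline 3-h drift of an empty droplet (pH units).
#' @param cell_cv lognormal coefficient of variation of per-cell rates.
#' @param bleach_halflife photobleaching half-life of the cell label dyes (min).
#' @param noise_sigma additive Gaussian readout noise SD (intensity counts).
#' @param seed integer RNG seed; identical seed and parameters give
#'   bit-identical stacks and truth tables.
#' @param ph0 initial droplet pH at t = 0 (inside the probe working range).
#' @param cell_spot_sigma_px Gaussian width of a rendered cell (px).
#' @param cell_diameter_px excluded-volume diameter of a cell (px); two cells
#'   in a droplet never approach closer than this.
#' @param step_sd_px RMS frame-to-frame Brownian displacement of a cell (px).
#' @param spot_amplitude peak label intensity of a cell at t = 0 (counts).
#' @param probe_gain detector gain mapping probe emission units to counts.
#' @param background_frac background level as a fraction of the 16-bit range.
#' @param bit_depth TIFF bit depth for written stacks: 16 (default) or 32
#'   (IEEE float, for validation work where quantization matters).
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(lambda_cells = 1.716, frac_hg = 0.5,
                         dph_mean_hg_single = 0.17,
                         dph_mean_ut_single = 0.17 / 2.6,
                         dph_empty = 0.17 / 8,
                         cell_cv = 0.4, bleach_halflife = 90,
                         noise_sigma = 500, seed = 1L,
                         ph0 = 6.4, cell_spot_sigma_px = 3,
                         cell_diameter_px = 12, step_sd_px = 2,
                         spot_amplitude = 15000, probe_gain = 12000,
                         background_frac = 0.05, bit_depth = 16L) {
  check_number(lambda_cells, "lambda_cells", min = 0)
  check_number(frac_hg, "frac_hg", min = 0, max = 1)
  check_number(dph_mean_hg_single, "dph_mean_hg_single", min = 0)
  check_number(dph_mean_ut_single, "dph_mean_ut_single", min = 0)
  check_number(dph_empty, "dph_empty", min = 0)
  check_number(cell_cv, "cell_cv", min = 0)
  check_number(bleach_halflife, "bleach_halflife", min = .Machine$double.eps)
  check_number(noise_sigma, "noise_sigma", min = 0)
  check_number(ph0, "ph0")
  check_number(seed, "seed")
  if (!bit_depth %in% c(16L, 32L)) stop2("bit_depth must be 16 or 32")
  structure(list(
    lambda_cells = lambda_cells, frac_hg = frac_hg,
    dph_mean_hg_single = dph_mean_hg_single,
    dph_mean_ut_single = dph_mean_ut_single,
    dph_empty = dph_empty, cell_cv = cell_cv,
    bleach_halflife = bleach_halflife, noise_sigma = noise_sigma,
    seed = as.integer(seed), ph0 = ph0,
    cell_spot_sigma_px = cell_spot_sigma_px,
    cell_diameter_px = cell_diameter_px, step_sd_px = step_sd_px,
    spot_amplitude = spot_amplitude, probe_gain = probe_gain,
    background_frac = background_frac, bit_depth = as.integer(bit_depth)
  ), class = "synth_params")
}

#' Acquisition geometry and cadence
#'
#' Geometry of one imaging run: a regular grid of microwells per imaging
#' window (13 x 13 by default, each window one stage position), droplet size,
#' pixel calibration and the time-lapse cadence (a frame every 5 min for 3 h
#' gives 37 frames including t = 0).
#'
#' @param grid_rows,grid_cols wells per imaging window.
#' @param n_positions number of imaging windows (3 is the desk-scale default;
#'   a full device has 240).
#' @param droplet_diameter_um droplet diameter in micrometres.
#' @param pixel_size_um micrometres per pixel (the 10x-objective pixel
#'   calibration is a free choice; 1 um/px gives 60 px droplets).
#' @param frame_interval_min minutes between frames.
#' @param duration_min total observation time in minutes.
#' @param channels ordered channel names.
#' @param well_pitch_factor centre-to-centre well pitch as a multiple of the
#'   droplet diameter; determines the rendered window size.
#' @return An object of class `acquisition_config` with derived fields
#'   `droplet_diameter_px`, `well_pitch_px`, `width`, `height`, `n_frames`,
#'   and `times` (min).
#' @export
acquisition_config <- function(grid_rows = 13L, grid_cols = 13L,
                               n_positions = 3L,
                               droplet_diameter_um = 60,
                               pixel_size_um = 1,
                               frame_interval_min = 5,
                               duration_min = 180,
                               channels = c("GREEN", "UV", "CY3_600", "CY5_667"),
                               well_pitch_factor = 1.3) {
  check_number(grid_rows, "grid_rows", min = 1)
  check_number(grid_cols, "grid_cols", min = 1)
  check_number(n_positions, "n_positions", min = 1)
  check_number(droplet_diameter_um, "droplet_diameter_um",
               min = .Machine$double.eps)
  check_number(pixel_size_um, "pixel_size_um", min = .Machine$double.eps)
  check_number(frame_interval_min, "frame_interval_min",
               min = .Machine$double.eps)
  check_number(duration_min, "duration_min", min = 0)
  if (well_pitch_factor <= 1) stop2("well_pitch_factor must exceed 1")
  d_px <- droplet_diameter_um / pixel_size_um
  pitch <- round(d_px * well_pitch_factor)
  times <- seq(0, duration_min, by = frame_interval_min)
  structure(list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    n_positions = as.integer(n_positions),
    droplet_diameter_um = droplet_diameter_um,
    pixel_size_um = pixel_size_um,
    frame_interval_min = frame_interval_min, duration_min = duration_min,
    channels = channels, well_pitch_factor = well_pitch_factor,
    droplet_diameter_px = d_px, well_pitch_px = pitch,
    width = as.integer(pitch * grid_cols),
    height = as.integer(pitch * grid_rows),
    n_frames = length(times), times = times
  ), class = "acquisition_config")
}

#' Sample Poisson cell occupancy
#'
#' Draws the number of cells per droplet from a Poisson distribution: when
#' cells at concentration c are partitioned into droplets of volume V, the
#' count per droplet is Poisson with mean \eqn{\lambda = cV}.
#'
#' @param lambda_cells mean cells per droplet (>= 0).
#' @param n_droplets number of droplets (>= 1).
#' @param seed optional seed; when supplied the draw is reproducible.
#' @return Integer vector of cell counts, length `n_droplets`.
#' @export
sample_occupancy <- function(lambda_cells, n_droplets, seed = NULL) {
  check_number(lambda_cells, "lambda_cells", min = 0)
  check_number(n_droplets, "n_droplets", min = 1)
  if (!is.null(seed)) set.seed(seed)
  stats::rpois(n_droplets, lambda_cells)
}

# Per-cell 3-h acidification drops: lognormal with the requested mean and CV.
draw_cell_rates <- function(n, mean_drop, cv) {
  if (n == 0L) return(numeric(0))
  if (cv == 0 || mean_drop == 0) return(rep(mean_drop, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean_drop) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a droplet pH trajectory
#'
#' Extracellular pH of a droplet over time: linear-in-time acidification whose
#' total 3-h drop is the sum of the per-cell drops plus the empty-droplet
#' drift. Per-cell drops default to lognormal draws (mean set by the emulsion,
#' CV by `params$cell_cv`). The model is additive by construction: an n-cell
#' droplet drops by the sum of its cells' individual contributions.
#'
#' @param cell_count number of cells in the droplet.
#' @param emulsion `"HG"` or `"UT"`; selects the per-cell mean drop.
#' @param per_cell_rates optional vector of per-cell total drops (pH units over
#'   the full duration); drawn if `NULL`.
#' @param times strictly increasing times in minutes, starting at 0.
#' @param params a [synth_params()] (supplies ph0, means, CV, drift).
#' @return Numeric vector of pH per time point. Attribute `"rates"` carries the
#'   per-cell drops used; attribute `"flag"` is `"out_of_range"` when the
#'   trajectory leaves the probe working range [5.0, 6.5] (flagged, not
#'   clipped).
#' @export
simulate_ph_trajectory <- function(cell_count, emulsion = c("HG", "UT"),
                                   per_cell_rates = NULL, times,
                                   params = synth_params()) {
  emulsion <- match.arg(emulsion)
  check_number(cell_count, "cell_count", min = 0)
  if (length(times) < 1L || times[1] != 0 ||
      (length(times) > 1L && any(diff(times) <= 0)))
    stop2("times must be strictly increasing and start at 0")
  if (params$ph0 < 5.0 || params$ph0 > 6.5)
    stop2("initial pH must lie inside the probe working range [5.0, 6.5]")
  if (is.null(per_cell_rates)) {
    mean_single <- if (emulsion == "HG") params$dph_mean_hg_single
                   else params$dph_mean_ut_single
    # per-cell contribution: the single-cell droplet mean minus the baseline
    # drift, so that a single-cell droplet's total mean drop equals the
    # configured value
    mean_cell <- max(mean_single - params$dph_empty, 0)
    per_cell_rates <- draw_cell_rates(cell_count, mean_cell, params$cell_cv)
  }
  if (length(per_cell_rates) != cell_count)
    stop2("per_cell_rates must have one entry per cell")
  total_drop <- sum(per_cell_rates) + params$dph_empty
  span <- max(times)
  frac <- if (span > 0) times / span else times * 0
  ph <- params$ph0 - total_drop * frac
  attr(ph, "rates") <- per_cell_rates
  attr(ph, "flag") <- if (any(ph < 5.0 | ph > 6.5)) "out_of_range" else "ok"
  ph
}

# Place n cell centres (offsets from the droplet centre, px) with pairwise
# minimum separation min_sep, preferentially near the centre: cells sediment
# to the bottom of a spherical droplet, which projects close to the 2-D
# centre. The settling radius expands if a packing cannot be found.
place_cells <- function(n, droplet_radius, min_sep) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  for (settle_frac in seq(0.5, 0.95, by = 0.15)) {
    r_max <- settle_frac * droplet_radius
    pts <- matrix(NA_real_, n, 2)
    ok <- TRUE
    for (k in seq_len(n)) {
      placed <- FALSE
      for (attempt in 1:200) {
        # truncated Gaussian radial placement biased to the centre
        p <- stats::rnorm(2, 0, 0.3 * droplet_radius)
        if (sqrt(sum(p^2)) > r_max) next
        if (k > 1) {
          d <- sqrt(rowSums((pts[1:(k - 1), , drop = FALSE] -
                               matrix(p, k - 1, 2, byrow = TRUE))^2))
          if (any(d < min_sep)) next
        }
        pts[k, ] <- p
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pts)
  }
  # dense occupancy from the Poisson tail: relax the separation gradually
  # (cells deform when crowded) rather than fail the render
  if (min_sep > 2)
    return(place_cells(n, droplet_radius, 0.8 * min_sep))
  stop2("could not place ", n, " cells with separation ", min_sep,
        " inside a droplet of radius ", droplet_radius)
}

# Confined Brownian walk for all cells of one droplet: per-frame Gaussian
# steps with RMS displacement step_sd (per-axis SD step_sd/sqrt(2)),
# reflection at 0.95 x droplet radius, excluded-volume rejection.
walk_cells <- function(start, n_frames, step_sd, droplet_radius, min_sep) {
  n <- nrow(start)
  out <- array(NA_real_, c(n, 2, n_frames))
  out[, , 1] <- start
  if (n_frames == 1L) return(out)
  rmax <- 0.95 * droplet_radius
  cur <- start
  for (f in 2:n_frames) {
    for (k in seq_len(n)) {
      p <- cur[k, ] + stats::rnorm(2, 0, step_sd / sqrt(2))
      rr <- sqrt(sum(p^2))
      if (rr > rmax) p <- p * (2 * rmax - rr) / rr  # reflect at the wall
      if (n > 1) {
        others <- cur[-k, , drop = FALSE]
        d <- sqrt(rowSums((others - matrix(p, n - 1, 2, byrow = TRUE))^2))
        if (any(d < min_sep)) p <- cur[k, ]  # rejected step: stay put
      }
      cur[k, ] <- p
    }
    out[, , f] <- cur
  }
  out
}

# Render one position; returns stacks (list of per-channel frame lists) and
# the truth tables. All coordinates are 0-based pixel centres.
render_position <- function(params, config, position,
                            cal = calibration_model()) {
  set.seed(derive_seed(params$seed, position))
  R <- config$grid_rows; C <- config$grid_cols
  pitch <- config$well_pitch_px
  radius <- config$droplet_diameter_px / 2
  if (params$cell_spot_sigma_px >= radius)
    stop2("cell spot radius must be smaller than the droplet radius")
  n_drop <- R * C
  grid <- expand.grid(col = 0:(C - 1), row = 0:(R - 1))
  cx <- (grid$col + 0.5) * pitch - 0.5
  cy <- (grid$row + 0.5) * pitch - 0.5
  emulsion <- ifelse(stats::runif(n_drop) < params$frac_hg, "HG", "UT")
  counts <- sample_occupancy(params$lambda_cells, n_drop)
  times <- config$times
  nf <- config$n_frames
  bg <- params$background_frac * MAX_COUNT

  ph <- matrix(NA_real_, n_drop, nf)
  rates <- vector("list", n_drop)
  for (d in seq_len(n_drop)) {
    tr <- simulate_ph_trajectory(counts[d], emulsion[d], times = times,
                                 params = params)
    ph[d, ] <- tr
    rates[[d]] <- attr(tr, "rates")
  }

  # cell motion
  cells <- list()
  for (d in seq_len(n_drop)) {
    if (counts[d] == 0L) next
    start <- place_cells(counts[d], radius, params$cell_diameter_px)
    pos <- walk_cells(start, nf, params$step_sd_px, radius,
                      params$cell_diameter_px)
    cells[[length(cells) + 1L]] <- list(droplet = d, pos = pos)
  }

  inten <- probe_intensities(as.vector(ph), cal, gain = params$probe_gain)
  F600 <- matrix(inten$F600, n_drop, nf)
  F667 <- matrix(inten$F667, n_drop, nf)

  disc_px <- lapply(seq_len(n_drop), function(d)
    disc_indices(cx[d], cy[d], radius, config$height, config$width))

  decay <- 2^(-times / params$bleach_halflife)
  stacks <- list()
  for (ch in config$channels) {
    frames <- vector("list", nf)
    for (f in seq_len(nf)) {
      m <- matrix(bg, config$height, config$width)
      if (ch %in% c("CY3_600", "CY5_667")) {
        vals <- if (ch == "CY3_600") F600[, f] else F667[, f]
        for (d in seq_len(n_drop)) m[disc_px[[d]]] <- bg + vals[d]
      } else {
        lab <- if (ch == "GREEN") "HG" else "UT"
        amp <- params$spot_amplitude * decay[f]
        for (cl in cells) {
          d <- cl$droplet
          if (emulsion[d] != lab) next
          for (k in seq_len(nrow(cl$pos[, , f, drop = FALSE]))) {
            m <- add_spot(m, cx[d] + cl$pos[k, 1, f], cy[d] + cl$pos[k, 2, f],
                          amp, params$cell_spot_sigma_px)
          }
        }
      }
      if (params$noise_sigma > 0)
        m <- m + matrix(stats::rnorm(length(m), 0, params$noise_sigma),
                        nrow(m), ncol(m))
      frames[[f]] <- pmin(pmax(m, 0), MAX_COUNT)
    }
    stacks[[ch]] <- frames
  }

  truth_droplets <- data.frame(
    position = position, row = grid$row, col = grid$col,
    x = cx, y = cy, radius = radius,
    emulsion = emulsion, n_cells = counts,
    dph_true = vapply(rates, sum, 0) + params$dph_empty,
    ph0 = params$ph0,
    stringsAsFactors = FALSE
  )
  truth_cells <- do.call(rbind, lapply(cells, function(cl) {
    d <- cl$droplet
    n <- dim(cl$pos)[1]
    data.frame(
      position = position, row = grid$row[d], col = grid$col[d],
      cell = rep(seq_len(n), each = nf),
      frame = rep(seq_len(nf), times = n),
      x = cx[d] + as.vector(t(cl$pos[, 1, ])),
      y = cy[d] + as.vector(t(cl$pos[, 2, ])),
      emulsion = emulsion[d],
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(truth_cells))
    truth_cells <- data.frame(position = integer(0), row = integer(0),
                              col = integer(0), cell = integer(0),
                              frame = integer(0), x = numeric(0),
                              y = numeric(0), emulsion = character(0))
  truth_ph <- data.frame(
    position = position,
    row = rep(grid$row, nf), col = rep(grid$col, nf),
    frame = rep(seq_len(nf), each = n_drop),
    time_min = rep(times, each = n_drop),
    ph_true = as.vector(ph)
  )
  list(stacks = stacks, truth_droplets = truth_droplets,
       truth_cells = truth_cells, truth_ph = truth_ph)
}

#' Render a ground-truthed synthetic dataset
#'
#' Generates multi-frame image stacks for every position and channel of an
#' acquisition, together with truth tables. Droplets are uniform bright disks
#' in the two probe channels, with intensities given by the forward
#' calibration at the simulated pH; cells are Gaussian spots undergoing
#' confined Brownian motion, visible only in the label channel of their
#' emulsion (HG in GREEN, UT in UV) and bleaching exponentially.
#'
#' @param params a [synth_params()].
#' @param config an [acquisition_config()].
#' @param out_dir output directory; stacks are written as
#'   `pos{P}_{CHANNEL}.tif`, truth tables as `truth_droplets.csv`,
#'   `truth_cells.csv`, `truth_ph.csv`, and the parameters are echoed to
#'   `synth_config.yaml`. When `NULL`, stacks are returned in memory (only
#'   advisable for small configurations).
#' @param cal forward [calibration_model()] used to render probe intensities.
#' @return Invisibly, a list with `truth_droplets`, `truth_cells`, `truth_ph`,
#'   and either `files` (manifest of written stacks) or `positions` (in-memory
#'   stacks).
#' @export
render_dataset <- function(params, config = acquisition_config(),
                           out_dir = NULL, cal = calibration_model()) {
  stopifnot(inherits(params, "synth_params"),
            inherits(config, "acquisition_config"))
  td <- list(); tc <- list(); tp <- list()
  positions <- list(); files <- NULL
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (p in seq_len(config$n_positions)) {
    rp <- render_position(params, config, p, cal)
    td[[p]] <- rp$truth_droplets; tc[[p]] <- rp$truth_cells
    tp[[p]] <- rp$truth_ph
    if (is.null(out_dir)) {
      positions[[p]] <- rp$stacks
    } else {
      for (ch in names(rp$stacks)) {
        path <- file.path(out_dir, sprintf("pos%03d_%s.tif", p, ch))
        write_stack(rp$stacks[[ch]], path, bit_depth = params$bit_depth)
        files <- rbind(files, data.frame(position = p, channel = ch,
                                         path = path,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  out <- list(truth_droplets = do.call(rbind, td),
              truth_cells = do.call(rbind, tc),
              truth_ph = do.call(rbind, tp))
  if (is.null(out_dir)) {
    out$positions <- positions
  } else {
    out$files <- files
    utils::write.csv(out$truth_droplets,
                     file.path(out_dir, "truth_droplets.csv"),
                     row.names = FALSE)
    utils::write.csv(out$truth_cells,
                     file.path(out_dir, "truth_cells.csv"), row.names = FALSE)
    utils::write.csv(out$truth_ph,
                     file.path(out_dir, "truth_ph.csv"), row.names = FALSE)
    yaml::write_yaml(list(synth = unclass(params),
                          acquisition = unclass(config)[seq_len(9)]),
                     file.path(out_dir, "synth_config.yaml"))
  }
  invisible(out)
}

#' Read a multi-frame TIFF stack
#'
#' @param path path to a (possibly multi-page) TIFF file.
#' @return A list of numeric matrices in intensity counts (0--65535).
#' @export
read_stack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  lapply(frames, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m * MAX_COUNT
  })
}

#' Write a multi-frame TIFF stack
#'
#' @param frames list of numeric matrices in intensity counts (0--65535).
#' @param path output path.
#' @param bit_depth 16 (unsigned) or 32 (IEEE float).
#' @export
write_stack <- function(frames, path, bit_depth = 16L) {
  if (!bit_depth %in% c(16L, 32L)) stop2("bit_depth must be 16 or 32")
  scaled <- lapply(frames, function(m) pmin(pmax(m, 0), MAX_COUNT) / MAX_COUNT)
  tiff::writeTIFF(scaled, path, bits.per.sample = as.integer(bit_depth))
  invisible(path)
}
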