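#' Build a labelled droplet mask from a probe-channel frame
#'
#' Droplets carry the fluorescent pH probe and appear as uniformly bright
#' disks in the 667 nm channel, so a single frame suffices to segment them:
#' automatic (Otsu) histogram thresholding, hole filling, removal of
#' components smaller than 25% of the expected droplet area, and connected
#' component labelling.
#'
#' @param frame numeric matrix in intensity counts (typically the first
#'   667 nm frame of a position).
#' @param expected_diameter_px expected droplet diameter in pixels.
#' @return Integer matrix of the same size: 0 is background, 1..n label the
#'   droplets. A mask with zero components triggers a warning (wrong channel
#'   or failed probe staining), not an error.
#' @export
build_droplet_mask <- function(frame, expected_diameter_px) {
  if (!is.matrix(frame)) stop2("frame must be a 2-D matrix")
  check_number(expected_diameter_px, "expected_diameter_px",
               min = .Machine$double.eps)
  rng <- range(frame)
  if (rng[1] == rng[2]) {
    warning("no droplets found: frame is constant")
    return(matrix(0L, nrow(frame), ncol(frame)))
  }
  scaled <- (frame - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  bw <- EBImage::fillHull(EBImage::Image(scaled > thr))
  lab <- EBImage::bwlabel(bw)
  lab <- EBImage::imageData(lab)
  min_area <- 0.25 * pi * (expected_diameter_px / 2)^2
  areas <- tabulate(lab[lab > 0])
  small <- which(areas < min_area)
  if (length(small)) lab[lab %in% small] <- 0L
  # relabel sequentially
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0L) {
    warning("no droplets found after area filtering")
    return(matrix(0L, nrow(frame), ncol(frame)))
  }
  relab <- integer(max(ids)); relab[ids] <- seq_along(ids)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- relab[lab[nz]]
  out
}

#' Index segmented droplets onto the microwell grid
#'
#' Sorts droplet centroids into grid rows by y (clusters split at gaps larger
#' than half the row pitch), then into columns by x, assigning each droplet
#' its (row, col) well index. Missing wells are reported; droplets whose disk
#' touches the image border are flagged (they are excluded from downstream
#' statistics by default, since detection near the window edge is
#' unreliable).
#'
#' @param mask labelled mask from [build_droplet_mask()].
#' @param grid_rows,grid_cols expected wells per window.
#' @param position position id used in messages and the output.
#' @return A data.frame of droplet records: `position`, `row`, `col` (0-based
#'   grid indices), `x`, `y` (0-based centroid), `radius` (equivalent-area
#'   px), `label` (mask label), `border_flag`. Missing grid slots are
#'   attached as attribute `"missing_slots"`.
#' @export
index_wells <- function(mask, grid_rows, grid_cols, position = 1L) {
  n <- max(mask)
  if (n == 0L)
    return(structure(data.frame(position = integer(0), row = integer(0),
                                col = integer(0), x = numeric(0),
                                y = numeric(0), radius = numeric(0),
                                label = integer(0), border_flag = logical(0)),
                     missing_slots = expand.grid(row = 0:(grid_rows - 1),
                                                 col = 0:(grid_cols - 1))))
  if (n > grid_rows * grid_cols)
    stop2("position ", position, ": found ", n,
          " droplet components for ", grid_rows * grid_cols, " grid slots")
  nz <- which(mask > 0)
  labs <- factor(mask[nz], levels = seq_len(n))
  ii <- ((nz - 1L) %% nrow(mask)) + 1L
  jj <- ((nz - 1L) %/% nrow(mask)) + 1L
  cy <- as.numeric(tapply(ii, labs, mean)) - 1  # 0-based, in label order 1..n
  cx <- as.numeric(tapply(jj, labs, mean)) - 1
  area <- tabulate(as.integer(labs), nbins = n)
  keep_lab <- area > 0
  cy <- cy[keep_lab]; cx <- cx[keep_lab]
  radius <- sqrt(area[keep_lab] / pi)
  ids <- seq_len(n)[keep_lab]

  pitch_y <- nrow(mask) / grid_rows
  pitch_x <- ncol(mask) / grid_cols
  rcl <- cluster_1d(as.numeric(cy), pitch_y)
  ccl <- cluster_1d(as.numeric(cx), pitch_x)
  rcent <- tapply(as.numeric(cy), rcl, mean)
  ccent <- tapply(as.numeric(cx), ccl, mean)
  row_idx <- round((rcent - min(rcent)) / pitch_y)
  col_idx <- round((ccent - min(ccent)) / pitch_x)
  row <- as.integer(row_idx[as.character(rcl)])
  col <- as.integer(col_idx[as.character(ccl)])
  if (any(row >= grid_rows) || any(col >= grid_cols))
    stop2("position ", position, ": droplet centroids do not fit the ",
          grid_rows, " x ", grid_cols, " grid")
  slot <- paste(row, col)
  if (anyDuplicated(slot))
    stop2("position ", position, ": multiple droplets indexed to well (",
          paste(slot[duplicated(slot)][1]), ")")

  border_flag <- (cx - radius < 0) | (cx + radius > ncol(mask) - 1) |
    (cy - radius < 0) | (cy + radius > nrow(mask) - 1)

  rec <- data.frame(position = position, row = row, col = col,
                    x = as.numeric(cx), y = as.numeric(cy),
                    radius = as.numeric(radius), label = ids,
                    border_flag = as.logical(border_flag))
  rec <- rec[order(rec$row, rec$col), ]
  rownames(rec) <- NULL
  all_slots <- expand.grid(col = 0:(grid_cols - 1), row = 0:(grid_rows - 1))
  missing <- all_slots[!paste(all_slots$row, all_slots$col) %in% slot,
                       c("row", "col")]
  if (nrow(missing) > 0L)
    message("position ", position, ": ", nrow(missing),
            " grid slot(s) without a droplet")
  attr(rec, "missing_slots") <- missing
  rec
}

#' Assign tracked cells to droplets (central-area rule)
#'
#' A track is assigned to a droplet when its median position over frames lies
#' within the central `central_fraction` of the droplet area, i.e. within
#' radius x sqrt(central_fraction) of the centre (~0.775 R for the default
#' 60% area). Tracks whose median falls in the outer annulus are discarded as
#' potential boundary artifacts (the detector tends to misread high-contrast
#' patches at the droplet rim as cells); tracks in no droplet are counted in
#' a diagnostics bin. Tracks observed in fewer than `min_track_frames` frames
#' are ignored as transient spurious detections.
#'
#' @param tracks a `cell_tracks` data.frame with a `channel` column
#'   (`"GREEN"`/`"UV"`), as produced by [track_stack()] for each label
#'   channel (rbind the two channels).
#' @param records droplet records from [index_wells()].
#' @param central_fraction fraction of droplet AREA considered central
#'   (default 0.60). Set `rule = "radius"` to interpret it as a radius
#'   fraction instead.
#' @param min_track_frames minimum number of frames a track must span.
#' @param rule `"area"` (default) or `"radius"`.
#' @details Occupancy is the maximum number of temporally co-existing tracks
#'   assigned to the droplet in each channel: two cells in a droplet are both
#'   detected in every frame, whereas fragments of one interrupted track never
#'   overlap in time (a cell cannot be in two places at once), so concurrency
#'   counts cells robustly even when a trajectory is split by missed
#'   detections.
#' @return `records` with per-channel occupancy columns `n_green`, `n_uv`;
#'   attribute `"diagnostics"` tallies assigned / annulus-discarded /
#'   unassigned / short tracks.
#' @export
assign_cells <- function(tracks, records, central_fraction = 0.60,
                         min_track_frames = 5L, rule = c("area", "radius")) {
  rule <- match.arg(rule)
  check_number(central_fraction, "central_fraction",
               min = .Machine$double.eps, max = 1)
  factor <- if (rule == "area") sqrt(central_fraction) else central_fraction
  records$n_green <- 0L
  records$n_uv <- 0L
  diag_counts <- c(assigned = 0L, annulus = 0L, unassigned = 0L, short = 0L)
  spans <- list()  # per record x channel: track frame spans
  if (nrow(tracks) > 0L) {
    if (is.null(tracks$channel)) stop2("tracks need a channel column")
    key <- paste(tracks$channel, tracks$track_id)
    for (k in unique(key)) {
      sel <- key == k
      if (sum(sel) < min_track_frames) {
        diag_counts["short"] <- diag_counts["short"] + 1L
        next
      }
      mx <- stats::median(tracks$x[sel])
      my <- stats::median(tracks$y[sel])
      d <- sqrt((records$x - mx)^2 + (records$y - my)^2)
      i <- which.min(d)
      if (length(i) == 0L || d[i] > records$radius[i]) {
        diag_counts["unassigned"] <- diag_counts["unassigned"] + 1L
      } else if (d[i] > factor * records$radius[i]) {
        diag_counts["annulus"] <- diag_counts["annulus"] + 1L
      } else {
        ch <- tracks$channel[sel][1]
        sk <- paste(i, ch)
        spans[[sk]] <- rbind(spans[[sk]], range(tracks$frame[sel]))
        diag_counts["assigned"] <- diag_counts["assigned"] + 1L
      }
    }
    # occupancy = maximum concurrency of the assigned track spans
    for (sk in names(spans)) {
      sp <- spans[[sk]]
      occ <- max_concurrency(sp[, 1], sp[, 2])
      parts <- strsplit(sk, " ")[[1]]
      i <- as.integer(parts[1])
      if (parts[2] == "GREEN") records$n_green[i] <- occ
      else records$n_uv[i] <- occ
    }
  }
  attr(records, "diagnostics") <- diag_counts
  records
}

# Maximum number of [start, end] intervals covering any single point.
max_concurrency <- function(start, end) {
  ev <- rbind(cbind(start, 1L), cbind(end + 1L, -1L))
  ev <- ev[order(ev[, 1], -ev[, 2]), , drop = FALSE]
  max(cumsum(ev[, 2]))
}

#' Classify droplet occupancy with cross-channel reconciliation
#'
#' Combines the occupancy counts from both label channels: a droplet that
#' looks empty in the green image may hold a violet-labelled cell, so the
#' total count decides the class and the channel of the cell decides the
#' emulsion. 0 cells: EMPTY/NONE; 1 cell: SINGLE with the emulsion of its
#' channel; 2+ cells: MULTI with the majority channel's emulsion,
#' mixed-channel droplets flagged.
#'
#' @param n_green,n_uv per-droplet occupancy counts (equal-length integer
#'   vectors, non-negative).
#' @param channel_map named map from channel to emulsion; the default follows
#'   the staining scheme green = HG (Calcein AM), UV = UT (CellTrace Violet).
#' @return data.frame with columns `class` (`EMPTY`/`SINGLE`/`MULTI`),
#'   `emulsion` (`HG`/`UT`/`NONE`), `mixed_flag`.
#' @export
classify_occupancy <- function(n_green, n_uv,
                               channel_map = c(GREEN = "HG", UV = "UT")) {
  if (length(n_green) != length(n_uv))
    stop2("n_green and n_uv must have the same length")
  if (any(n_green < 0) || any(n_uv < 0))
    stop2("occupancy counts must be non-negative")
  total <- n_green + n_uv
  class <- ifelse(total == 0L, "EMPTY", ifelse(total == 1L, "SINGLE", "MULTI"))
  emulsion <- ifelse(total == 0L, "NONE",
                     ifelse(n_green >= n_uv, channel_map[["GREEN"]],
                            channel_map[["UV"]]))
  mixed_flag <- n_green > 0L & n_uv > 0L
  data.frame(class = class, emulsion = emulsion, mixed_flag = mixed_flag,
             stringsAsFactors = FALSE)
}

#' Segment, index and classify the droplets of one position
#'
#' Convenience wrapper: builds the droplet mask from the first 667 nm frame
#' (droplets are immobilized in their wells, so a single static mask serves
#' all frames; set `per_frame = TRUE` to re-mask every frame and use the
#' first frame's indexing), indexes the wells, assigns the tracked cells and
#' classifies occupancy.
#'
#' @param cy5_stack list of 667 nm frames.
#' @param tracks combined `cell_tracks` for the GREEN and UV channels.
#' @param config an [acquisition_config()].
#' @param position position id.
#' @param central_fraction,min_track_frames see [assign_cells()].
#' @param channel_map see [classify_occupancy()].
#' @param per_frame logical; re-build the mask for every frame (mask list
#'   returned in attribute `"masks"`). The static frame-0 mask remains the
#'   one used for indexing.
#' @return Droplet records with occupancy and class columns; the labelled
#'   mask is attached as attribute `"mask"`.
#' @export
map_droplets <- function(cy5_stack, tracks, config, position = 1L,
                         central_fraction = 0.60, min_track_frames = 5L,
                         channel_map = c(GREEN = "HG", UV = "UT"),
                         per_frame = FALSE) {
  mask <- build_droplet_mask(cy5_stack[[1]], config$droplet_diameter_px)
  rec <- index_wells(mask, config$grid_rows, config$grid_cols, position)
  rec <- assign_cells(tracks, rec, central_fraction, min_track_frames)
  cls <- classify_occupancy(rec$n_green, rec$n_uv, channel_map)
  rec$class <- cls$class
  rec$emulsion <- cls$emulsion
  rec$mixed_flag <- cls$mixed_flag
  attr(rec, "mask") <- mask
  if (per_frame)
    attr(rec, "masks") <- lapply(cy5_stack, build_droplet_mask,
                                 expected_diameter_px =
                                   config$droplet_diameter_px)
  rec
}
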