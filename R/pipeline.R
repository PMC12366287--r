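#' Run configuration
#'
#' Bundles all stage parameters of one analysis run (real images or a
#' synthetic render) into a single serializable object.
#'
#' @param seed top-level integer seed; every source of randomness in the run
#'   (synthesis, crosstalk sampling) is derived from it.
#' @param out_dir output directory for all stage artifacts.
#' @param input_dir directory of input TIFF stacks; `NULL` with `synth` set
#'   means the run synthesizes its own input.
#' @param synth optional [synth_params()]; when set the pipeline generates
#'   the input stacks.
#' @param acquisition an [acquisition_config()].
#' @param tracker a [tracker_params()].
#' @param calibration a [calibration_model()].
#' @param qc a [qc_thresholds()].
#' @param channel_map named channel-to-emulsion map.
#' @param central_fraction central droplet area fraction for cell assignment.
#' @param min_track_frames minimum frames per accepted track.
#' @param filename_pattern regex with capture groups (position, channel) for
#'   multi-frame stack inputs.
#' @param log_level `"INFO"` or `"QUIET"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("acidrop_run_"),
                       input_dir = NULL,
                       synth = synth_params(seed = seed),
                       acquisition = acquisition_config(),
                       tracker = tracker_params(),
                       calibration = calibration_model(),
                       qc = qc_thresholds(),
                       channel_map = c(GREEN = "HG", UV = "UT"),
                       central_fraction = 0.60, min_track_frames = 5L,
                       filename_pattern =
                         "^pos(\\d+)_([A-Za-z0-9_]+)\\.tiff?$",
                       log_level = c("INFO", "QUIET")) {
  log_level <- match.arg(log_level)
  check_number(seed, "seed")
  if (is.null(input_dir) && is.null(synth))
    stop2("either input_dir or synth parameters must be provided")
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 input_dir = input_dir, synth = synth,
                 acquisition = acquisition, tracker = tracker,
                 calibration = calibration, qc = qc,
                 channel_map = channel_map,
                 central_fraction = central_fraction,
                 min_track_frames = as.integer(min_track_frames),
                 filename_pattern = filename_pattern,
                 log_level = log_level),
            class = "run_config")
}

log_info <- function(config, ...) {
  if (identical(config$log_level, "INFO"))
    message(format(Sys.time(), "%H:%M:%S"), " ", ...)
}

#' Write a run configuration to YAML
#'
#' @param config a [run_config()].
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  ser <- lapply(unclass(config), function(x) {
    if (inherits(x, "acquisition_config"))
      unclass(x)[c("grid_rows", "grid_cols", "n_positions",
                   "droplet_diameter_um", "pixel_size_um",
                   "frame_interval_min", "duration_min", "channels",
                   "well_pitch_factor")]
    else if (inherits(x, "calibration_model"))
      unclass(x)[c("pKa", "R_A", "R_B", "norm_factor", "mode", "ph_range")]
    else if (is.list(x)) unclass(x)
    else if (!is.null(names(x))) as.list(x)  # yaml drops vector names
    else x
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Reconstructs every component through its constructor, so invariants are
#' re-validated; unknown keys are rejected with a config error.
#'
#' @param path YAML file written by [write_run_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(fn, args, what) {
    tryCatch(do.call(fn, args),
             error = function(e) stop2("config error in ", what, ": ",
                                       conditionMessage(e)))
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop2("config error: unknown keys: ", paste(unknown, collapse = ", "))
  args <- raw
  if (!is.null(raw$synth))
    args$synth <- build(synth_params, raw$synth, "synth")
  if (!is.null(raw$acquisition))
    args$acquisition <- build(acquisition_config, raw$acquisition,
                              "acquisition")
  if (!is.null(raw$tracker))
    args$tracker <- build(tracker_params, raw$tracker, "tracker")
  if (!is.null(raw$calibration))
    args$calibration <- build(calibration_model, raw$calibration,
                              "calibration")
  if (!is.null(raw$qc)) args$qc <- build(qc_thresholds, raw$qc, "qc")
  if (!is.null(raw$channel_map)) args$channel_map <- unlist(raw$channel_map)
  build(run_config, args, "run_config")
}

#' Sort image files into a per-position, per-channel manifest
#'
#' Groups the files of an acquisition by stage position and channel with
#' frames in acquisition order. Two layouts are supported: multi-frame
#' stacks (`pos001_CY5_667.tif`) and one file per frame
#' (`pos001_CY5_667_t003.tif`, matched by `frame_pattern`). Files matching
#' neither pattern are listed in the `"unmatched"` attribute, not silently
#' dropped.
#'
#' @param input_dir directory to scan.
#' @param pattern regex for stack files with capture groups (position,
#'   channel).
#' @param frame_pattern regex for per-frame files with capture groups
#'   (position, channel, frame).
#' @return data.frame manifest (`position`, `channel`, `frame`, `path`)
#'   sorted by position, channel, frame; `frame` is `NA` for whole-stack
#'   files. Duplicate (position, channel, frame) triples are an error.
#' @export
sort_images <- function(input_dir,
                        pattern = "^pos(\\d+)_([A-Za-z0-9_]+)\\.tiff?$",
                        frame_pattern =
                          "^pos(\\d+)_([A-Za-z0-9_]+)_t(\\d+)\\.tiff?$") {
  files <- list.files(input_dir, pattern = "\\.tiff?$", ignore.case = TRUE)
  rows <- list(); unmatched <- character(0)
  for (f in files) {
    mf <- regmatches(f, regexec(frame_pattern, f))[[1]]
    ms <- regmatches(f, regexec(pattern, f))[[1]]
    if (length(mf) == 4L) {
      rows[[length(rows) + 1L]] <-
        data.frame(position = as.integer(mf[2]), channel = mf[3],
                   frame = as.integer(mf[4]),
                   path = file.path(input_dir, f), stringsAsFactors = FALSE)
    } else if (length(ms) == 3L) {
      rows[[length(rows) + 1L]] <-
        data.frame(position = as.integer(ms[2]), channel = ms[3],
                   frame = NA_integer_, path = file.path(input_dir, f),
                   stringsAsFactors = FALSE)
    } else {
      unmatched <- c(unmatched, f)
    }
  }
  man <- if (length(rows)) do.call(rbind, rows)
  else data.frame(position = integer(0), channel = character(0),
                  frame = integer(0), path = character(0),
                  stringsAsFactors = FALSE)
  if (nrow(man) == 0L) warning("no image files matched in ", input_dir)
  key <- paste(man$position, man$channel, man$frame)
  if (anyDuplicated(key))
    stop2("duplicate (position, channel, frame): ", key[duplicated(key)][1])
  man <- man[order(man$position, man$channel, man$frame), ]
  rownames(man) <- NULL
  if (length(unmatched)) {
    warning(length(unmatched), " file(s) did not match the filename pattern")
    attr(man, "unmatched") <- unmatched
  }
  man
}

load_position_stack <- function(manifest, position, channel) {
  sel <- manifest[manifest$position == position &
                    manifest$channel == channel, , drop = FALSE]
  if (nrow(sel) == 0L)
    stop2("no files for position ", position, " channel ", channel)
  if (nrow(sel) == 1L && is.na(sel$frame[1])) return(read_stack(sel$path))
  do.call(c, lapply(sel$path[order(sel$frame)], read_stack))
}

#' Run the full analysis pipeline
#'
#' Executes every stage end to end: optional synthetic rendering, cell
#' tracking in the GREEN/UV label channels, droplet segmentation and grid
#' indexing, central-area occupancy assignment with cross-channel
#' reconciliation, pH quantification from the probe channels,
#' \eqn{\Delta}pH QC, rates, and group statistics; all artifacts plus a
#' provenance record are written to `config$out_dir`. Re-running with the
#' same configuration is bit-reproducible for synthetic inputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `droplets`, `tracks`, `traces`,
#'   `summaries`, `qc` (report + rates), `group_stats`, `truth` (synthetic
#'   runs only), and `files` (paths of written artifacts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  acq <- config$acquisition
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  truth <- NULL
  if (!is.null(config$synth) && is.null(config$input_dir)) {
    log_info(config, "synthesizing ", acq$n_positions, " position(s)")
    synth <- config$synth
    synth$seed <- derive_seed(config$seed, 0L)
    img_dir <- file.path(out_dir, "images")
    truth <- render_dataset(synth, acq, img_dir, cal = config$calibration)
    input_dir <- img_dir
  } else {
    input_dir <- config$input_dir
  }
  manifest <- sort_images(input_dir, config$filename_pattern)
  positions <- sort(unique(manifest$position))

  all_tracks <- list(); all_records <- list()
  all_traces <- list(); all_summaries <- list()
  for (p in positions) {
    stage <- "tracking"
    res <- tryCatch({
      tracks <- do.call(rbind, lapply(c("GREEN", "UV"), function(ch) {
        track_stack(load_position_stack(manifest, p, ch), config$tracker,
                    channel = ch)
      }))
      stage <- "droplet indexing"
      cy5 <- load_position_stack(manifest, p, "CY5_667")
      rec <- map_droplets(cy5, tracks, acq, position = p,
                          central_fraction = config$central_fraction,
                          min_track_frames = config$min_track_frames,
                          channel_map = config$channel_map)
      stage <- "pH quantification"
      cy3 <- load_position_stack(manifest, p, "CY3_600")
      q <- quantify_ph(cy3, cy5, rec, config$calibration, acq$times)
      list(tracks = tracks, rec = rec, q = q)
    }, error = function(e) {
      stop2("pipeline failed at stage '", stage, "' for position ", p, ": ",
            conditionMessage(e))
    })
    tr <- res$tracks; tr$position <- p
    all_tracks[[as.character(p)]] <- tr
    all_records[[as.character(p)]] <- res$rec
    all_traces[[as.character(p)]] <- res$q$traces
    all_summaries[[as.character(p)]] <- res$q$summary
    log_info(config, "position ", p, ": ", nrow(res$rec), " droplets, ",
             length(unique(paste(tr$channel, tr$track_id))), " tracks, ",
             sum(res$rec$class == "SINGLE"), " single / ",
             sum(res$rec$class == "EMPTY"), " empty / ",
             sum(res$rec$class == "MULTI"), " multi")
  }
  tracks <- do.call(rbind, all_tracks)
  droplets <- do.call(rbind, all_records)
  traces <- do.call(rbind, all_traces)
  summaries <- do.call(rbind, all_summaries)
  rownames(droplets) <- rownames(traces) <- rownames(summaries) <- NULL

  qc <- apply_qc(summaries, config$qc)
  rates <- qc_rates(qc$summaries)
  group_stats <- group_statistics(qc$summaries)
  log_info(config, "QC: ",
           sum(qc$summaries$qc_status == "kept"), " kept of ",
           nrow(summaries), " droplets; pooled encapsulation efficiency ",
           sprintf("%.1f%%",
                   100 * rates$encapsulation_efficiency[
                     rates$position == "pooled"]))

  files <- c(
    tracks = write_csv_artifact(tracks, file.path(out_dir, "tracks.csv")),
    droplets = write_csv_artifact(droplets,
                                  file.path(out_dir, "droplets.csv")),
    ph_traces = write_csv_artifact(traces,
                                   file.path(out_dir, "ph_traces.csv")),
    droplet_summary = write_csv_artifact(
      qc$summaries, file.path(out_dir, "droplet_summary.csv")),
    group_stats = write_csv_artifact(group_stats,
                                     file.path(out_dir, "group_stats.csv"))
  )
  qc_json <- file.path(out_dir, "qc_report.json")
  jsonlite::write_json(list(report = qc$report, rates = rates), qc_json,
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  files["qc_report"] <- qc_json

  cfg_path <- file.path(out_dir, "run_config.yaml")
  write_run_config(config, cfg_path)
  prov <- list(
    package = "acidrop",
    version = as.character(utils::packageVersion("acidrop")),
    r_version = R.version.string,
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_positions = length(positions),
    timestamp_format = "deterministic outputs; see config_md5"
  )
  prov_path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE)
  files["provenance"] <- prov_path

  invisible(list(droplets = droplets, tracks = tracks, traces = traces,
                 summaries = qc$summaries, qc_report = qc$report,
                 rates = rates, group_stats = group_stats, truth = truth,
                 files = files))
}

write_csv_artifact <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Group statistics over QC-kept droplets
#'
#' Pairwise two-tailed Student's t-tests between the biologically meaningful
#' droplet groups (class x emulsion) on raw \eqn{\Delta}pH: HG vs UT single
#' cells, HG vs UT multi cells, and within each emulsion single vs multi and
#' single vs empty.
#'
#' @param summaries QC-amended droplet summaries (kept droplets are used).
#' @return data.frame with group names, sizes, means, SDs, t, p and the
#'   significance symbol; comparisons with fewer than 2 droplets per group
#'   are omitted.
#' @export
group_statistics <- function(summaries) {
  kept <- summaries[summaries$qc_status == "kept" &
                      !is.na(summaries$delta_ph), , drop = FALSE]
  grp <- function(cl, em) kept$delta_ph[kept$class == cl &
                                          kept$emulsion == em]
  pairs <- list(
    c("HG single", "SINGLE", "HG", "UT single", "SINGLE", "UT"),
    c("HG multi", "MULTI", "HG", "UT multi", "MULTI", "UT"),
    c("HG single", "SINGLE", "HG", "HG multi", "MULTI", "HG"),
    c("UT single", "SINGLE", "UT", "UT multi", "MULTI", "UT"),
    c("HG single", "SINGLE", "HG", "empty", "EMPTY", "NONE"),
    c("UT single", "SINGLE", "UT", "empty", "EMPTY", "NONE")
  )
  out <- list()
  for (p in pairs) {
    a <- grp(p[2], p[3]); b <- grp(p[5], p[6])
    if (length(a) < 2L || length(b) < 2L) next
    cg <- compare_groups(a, b)
    out[[length(out) + 1L]] <- data.frame(
      group_a = p[1], group_b = p[4], n_a = cg$n_a, n_b = cg$n_b,
      mean_a = cg$mean_a, mean_b = cg$mean_b, sd_a = cg$sd_a, sd_b = cg$sd_b,
      t = cg$t, p = cg$p, symbol = cg$symbol, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(group_a = character(0), group_b = character(0),
                      n_a = integer(0), n_b = integer(0),
                      mean_a = numeric(0), mean_b = numeric(0),
                      sd_a = numeric(0), sd_b = numeric(0), t = numeric(0),
                      p = numeric(0), symbol = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
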