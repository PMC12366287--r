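#' Raw-\eqn{\Delta}pH QC thresholds
#'
#' Windows applied to the raw pH drop of each droplet, conditional on its
#' image-derived class. Image-classified single-cell droplets are kept when
#' `single_min <= dpH <= single_max`, reclassified as debris-containing
#' empty droplets below the window and as multiple-cell droplets above it.
#' Image-classified empty droplets are kept when `dpH <= empty_max` and
#' flagged as errors (hidden cells with weak label fluorescence) above it.
#' The defaults are the windows derived for a glucose-rich run; they are
#' per-experiment configuration, since the dpH scale depends on the medium.
#'
#' @param single_min,single_max single-cell droplet window (pH units).
#' @param empty_max empty-droplet upper bound (pH units).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(single_min = 0.28, single_max = 1.02,
                          empty_max = 0.37) {
  check_number(single_min, "single_min")
  check_number(single_max, "single_max")
  check_number(empty_max, "empty_max", min = 0)
  if (single_min > single_max) stop2("single_min must be <= single_max")
  structure(list(single_min = single_min, single_max = single_max,
                 empty_max = empty_max), class = "qc_thresholds")
}

#' Apply \eqn{\Delta}pH QC windows to droplet summaries
#'
#' Partitions every droplet into exactly one QC bin based on its
#' image-derived class and raw pH drop (see [qc_thresholds()]). Droplets
#' without a defined drop are excluded with reason "no trace"; border-flagged
#' droplets are excluded up front when present.
#'
#' @param summaries data.frame with at least `class` and `delta_ph` columns
#'   (e.g. the summary from [quantify_ph()]).
#' @param thresholds a [qc_thresholds()].
#' @param exclude_border drop border-flagged droplets (default TRUE when a
#'   `border_flag` column is present).
#' @return A list: `summaries` (input plus `qc_status` and `qc_class`
#'   columns) and `report` (per-position and pooled counts of kept /
#'   reclassified / error / excluded droplets per input class, with
#'   per-class error rates).
#' @export
apply_qc <- function(summaries, thresholds = qc_thresholds(),
                     exclude_border = TRUE) {
  if (!all(c("class", "delta_ph") %in% names(summaries)))
    stop2("summaries need class and delta_ph columns")
  th <- thresholds
  n <- nrow(summaries)
  status <- rep("kept", n)
  qc_class <- summaries$class
  border <- if (exclude_border && !is.null(summaries$border_flag))
    summaries$border_flag else rep(FALSE, n)
  no_trace <- is.na(summaries$delta_ph)
  d <- summaries$delta_ph
  single <- summaries$class == "SINGLE"
  empty <- summaries$class == "EMPTY"
  status[single & !no_trace & d < th$single_min] <- "reclassified_empty"
  qc_class[single & !no_trace & d < th$single_min] <- "EMPTY"
  status[single & !no_trace & d > th$single_max] <- "reclassified_multi"
  qc_class[single & !no_trace & d > th$single_max] <- "MULTI"
  status[empty & !no_trace & d > th$empty_max] <- "error_hidden_cell"
  qc_class[empty & !no_trace & d > th$empty_max] <- "ERROR"
  status[no_trace] <- "excluded_no_trace"
  status[border] <- "excluded_border"
  summaries$qc_status <- status
  summaries$qc_class <- qc_class

  tally <- function(df, position) {
    do.call(rbind, lapply(unique(df$class), function(cl) {
      s <- df$qc_status[df$class == cl]
      n_in <- length(s)
      kept <- sum(s == "kept")
      recl <- sum(s %in% c("reclassified_empty", "reclassified_multi",
                           "error_hidden_cell"))
      excl <- sum(s %in% c("excluded_no_trace", "excluded_border"))
      data.frame(position = position, class = cl, n = n_in, kept = kept,
                 reclassified = recl, excluded = excl,
                 error_rate = if (n_in - excl > 0) recl / (n_in - excl)
                              else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  report <- tally(summaries, "pooled")
  if (!is.null(summaries$position)) {
    per_pos <- do.call(rbind, lapply(
      split(summaries, summaries$position),
      function(df) tally(df, as.character(df$position[1]))))
    report <- rbind(per_pos, report)
    rownames(report) <- NULL
  }
  list(summaries = summaries, report = report)
}

#' Error and encapsulation rates after QC
#'
#' Encapsulation efficiency is the fraction of all droplets that are kept
#' single-cell droplets after QC; the per-class error rate is the fraction
#' of QC-evaluated candidates of that class that were reclassified or
#' flagged.
#'
#' @param summaries QC-amended summaries from [apply_qc()].
#' @return data.frame with one row per position plus a pooled row: columns
#'   `n_droplets`, `kept_single`, `encapsulation_efficiency`,
#'   `single_error_rate`, `empty_error_rate`. Zero-droplet groups report
#'   `NA` rates.
#' @export
qc_rates <- function(summaries) {
  one <- function(df, position) {
    n <- nrow(df)
    eval_single <- sum(df$class == "SINGLE" &
                         !df$qc_status %in% c("excluded_no_trace",
                                              "excluded_border"))
    eval_empty <- sum(df$class == "EMPTY" &
                        !df$qc_status %in% c("excluded_no_trace",
                                             "excluded_border"))
    kept_single <- sum(df$class == "SINGLE" & df$qc_status == "kept")
    err_single <- sum(df$qc_status %in% c("reclassified_empty",
                                          "reclassified_multi"))
    err_empty <- sum(df$qc_status == "error_hidden_cell")
    data.frame(
      position = position, n_droplets = n, kept_single = kept_single,
      encapsulation_efficiency = if (n > 0) kept_single / n else NA_real_,
      single_error_rate = if (eval_single > 0) err_single / eval_single
                          else NA_real_,
      empty_error_rate = if (eval_empty > 0) err_empty / eval_empty
                         else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- one(summaries, "pooled")
  if (!is.null(summaries$position)) {
    per_pos <- do.call(rbind, lapply(
      split(summaries, summaries$position),
      function(df) one(df, as.character(df$position[1]))))
    out <- rbind(per_pos, out)
    rownames(out) <- NULL
  }
  out
}

#' Probe crosstalk ratio between positive and negative droplets
#'
#' Quantifies probe leakage by the ratio of mean emission intensities of
#' probe-containing ("positive") droplets to probe-free ("negative")
#' droplets over time, per wavelength, from a random sample of droplets
#' (default 3 of each, seeded for reproducibility). A stable ratio over the
#' observation window indicates no probe transfer between droplets.
#'
#' @param positive,negative lists with matrices `F600` and `F667`
#'   (droplets x timepoints) of mean droplet intensities.
#' @param times timepoints (min).
#' @param n_sample droplets sampled from each population (default 3).
#' @param seed optional RNG seed for the sampling.
#' @param stability_threshold maximum relative drift of the ratio from its
#'   initial value for a "stable" verdict (default 0.10).
#' @return A list of class `crosstalk_result`: `times`, `ratio` (timepoints
#'   x wavelengths), `sd` (across sampled droplet pairs), `stable` (named
#'   logical per wavelength), `drift` (max relative drift), `flagged`
#'   (timepoints where the negative mean was not positive).
#' @export
crosstalk_ratio <- function(positive, negative, times, n_sample = 3L,
                            seed = NULL, stability_threshold = 0.10) {
  for (nm in c("F600", "F667")) {
    if (is.null(positive[[nm]]) || is.null(negative[[nm]]))
      stop2("positive and negative need F600 and F667 matrices")
    if (nrow(positive[[nm]]) == 0L || nrow(negative[[nm]]) == 0L)
      stop2("both droplet populations must be non-empty")
  }
  if (!is.null(seed)) set.seed(seed)
  ip <- sample(nrow(positive$F600), n_sample,
               replace = nrow(positive$F600) < n_sample)
  ineg <- sample(nrow(negative$F600), n_sample,
                 replace = nrow(negative$F600) < n_sample)
  nt <- length(times)
  wl <- c("F600", "F667")
  ratio <- matrix(NA_real_, nt, 2, dimnames = list(NULL, wl))
  sdm <- matrix(NA_real_, nt, 2, dimnames = list(NULL, wl))
  flagged <- rep(FALSE, nt)
  for (w in wl) {
    P <- positive[[w]][ip, , drop = FALSE]
    N <- negative[[w]][ineg, , drop = FALSE]
    mn <- colMeans(N)
    bad <- !is.finite(mn) | mn <= 0
    flagged <- flagged | bad
    ratio[!bad, w] <- colMeans(P)[!bad] / mn[!bad]
    pair <- P / N  # per-sampled-pair ratios
    sdm[, w] <- apply(pair, 2, stats::sd)
    sdm[bad, w] <- NA_real_
  }
  drift <- apply(ratio, 2, function(r) {
    r <- r[is.finite(r)]
    if (length(r) < 2L) return(NA_real_)
    max(abs(r - r[1])) / abs(r[1])
  })
  structure(list(times = times, ratio = ratio, sd = sdm,
                 n_sample = n_sample,
                 stable = drift <= stability_threshold, drift = drift,
                 flagged = flagged),
            class = "crosstalk_result")
}

#' Poisson encapsulation design
#'
#' Mean cells per droplet \eqn{\lambda} = concentration x droplet volume,
#' and the resulting Poisson occupancy probabilities: empty
#' \eqn{P_0 = e^{-\lambda}}, single \eqn{P_1 = \lambda e^{-\lambda}},
#' multiple \eqn{1 - P_0 - P_1}.
#'
#' @param concentration_per_ml cell concentration in cells/mL.
#' @param droplet_volume_pl droplet volume in picolitres.
#' @return list with `lambda`, `p_empty`, `p_single`, `p_multi`.
#' @export
poisson_design <- function(concentration_per_ml, droplet_volume_pl) {
  check_number(concentration_per_ml, "concentration_per_ml", min = 0)
  check_number(droplet_volume_pl, "droplet_volume_pl",
               min = .Machine$double.eps)
  lambda <- concentration_per_ml * droplet_volume_pl * 1e-9  # pL -> mL
  p0 <- exp(-lambda)
  p1 <- lambda * exp(-lambda)
  list(lambda = lambda, p_empty = p0, p_single = p1,
       p_multi = 1 - p0 - p1)
}

#' Droplet volume from diameter
#'
#' Sphere volume \eqn{\pi d^3 / 6}, reported in picolitres.
#'
#' @param diameter_um droplet diameter in micrometres (> 0).
#' @return Volume in pL.
#' @export
droplet_volume <- function(diameter_um) {
  check_number(diameter_um, "diameter_um", min = .Machine$double.eps)
  pi * diameter_um^3 / 6 / 1000  # um^3 = fL; 1000 fL = 1 pL
}

#' Polydispersity of a droplet population
#'
#' Coefficient of variation of droplet diameters, in percent.
#'
#' @param diameters numeric vector of droplet diameters (>= 2 values).
#' @return `100 * sd / mean`.
#' @export
polydispersity <- function(diameters) {
  if (length(diameters) < 2L) stop2("need at least 2 diameters")
  m <- mean(diameters)
  if (m == 0) stop2("mean diameter is zero")
  100 * stats::sd(diameters) / m
}

#' Two-sample comparison with significance symbols
#'
#' Two-tailed two-sample Student's t-test (pooled variance), with the
#' conventional significance legend: ns for p > 0.05, * for p <= 0.05,
#' ** for p <= 0.01, *** for p <= 0.001.
#'
#' @param values_a,values_b numeric vectors (each n >= 2).
#' @return list with `t`, `df`, `p`, `symbol`, group means, SDs and sizes.
#' @export
compare_groups <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2L || nb < 2L) stop2("each group needs at least 2 values")
  ma <- mean(values_a); mb <- mean(values_b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(values_a) + (nb - 1) * stats::var(values_b)) /
    df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  diff <- ma - mb
  t <- if (se > 0) diff / se else if (diff == 0) 0 else sign(diff) * Inf
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, symbol = significance_symbol(p),
       mean_a = ma, mean_b = mb,
       sd_a = stats::sd(values_a), sd_b = stats::sd(values_b),
       n_a = na, n_b = nb)
}

#' Significance symbol for a p-value
#'
#' @param p p-value(s).
#' @return `"ns"`, `"*"`, `"**"` or `"***"`.
#' @export
significance_symbol <- function(p) {
  ifelse(p <= 0.001, "***",
         ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "ns")))
}
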