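#' Ratiometric probe calibration model
#'
#' Describes how the dual-emission pH probe maps pH to the ratio
#' \eqn{R = F_{600}/F_{667}} of its acid-form (600 nm) and base-form (667 nm)
#' emission intensities, and back. The probe is a weak acid: the acid form
#' dominates emission at 600 nm, the base form at 667 nm, and the ground-state
#' equilibrium between the two shifts with pH around \code{pKa}. The inverse
#' (standard dual-emission ratiometric) equation is
#' \deqn{pH = pKa - \log_{10}\!\left(\frac{R - R_B}{R_A - R}\cdot
#'   \mathrm{norm\_factor}\right)}
#' where \code{R_A} and \code{R_B} are the ratio endpoints at the fully acid
#' and fully basic limits and \code{norm_factor} is the base/acid intensity
#' ratio at 667 nm, the normalization constant of the manufacturer-style
#' equation.
#'
#' The default constants are synthetic-model defaults (chosen so that R is a
#' near-linear function of pH across the probe's working range 5.0--6.5, as a
#' real probe of this family behaves); they must be overridden with measured
#' endpoint values when analysing real probe data.
#'
#' @param pKa acid dissociation exponent of the probe (default 6.4).
#' @param R_A emission ratio at the acid endpoint.
#' @param R_B emission ratio at the basic endpoint.
#' @param norm_factor base/acid intensity ratio at 667 nm; must be > 0.
#' @param mode `"RATIOMETRIC"` (endpoint equation) or `"LINEAR"` (straight-line
#'   fit of R against pH over the working range).
#' @param ph_range working pH range of the probe, default `c(5.0, 6.5)`.
#' @param linear_slope,linear_intercept straight-line calibration; when `NULL`
#'   they are least-squares fitted from the ratiometric forward model over
#'   `ph_range`.
#' @return An object of class `calibration_model`.
#' @seealso [ph_from_ratio()], [ratio_from_ph()], [fit_linear_calibration()]
#' @export
calibration_model <- function(pKa = 6.4, R_A = 4.0, R_B = 0.2,
                              norm_factor = 4.0,
                              mode = c("RATIOMETRIC", "LINEAR"),
                              ph_range = c(5.0, 6.5),
                              linear_slope = NULL, linear_intercept = NULL) {
  mode <- match.arg(mode)
  check_number(pKa, "pKa")
  check_number(R_A, "R_A"); check_number(R_B, "R_B")
  check_number(norm_factor, "norm_factor", min = .Machine$double.eps)
  if (R_A == R_B) stop2("R_A and R_B must differ")
  if (length(ph_range) != 2L || ph_range[1] >= ph_range[2])
    stop2("ph_range must be an ordered pair")
  cal <- structure(list(
    pKa = pKa, R_A = R_A, R_B = R_B, norm_factor = norm_factor,
    mode = mode, ph_range = ph_range,
    linear_slope = linear_slope, linear_intercept = linear_intercept,
    linear_residual_sd = NA_real_, r_range = NULL
  ), class = "calibration_model")
  if (is.null(linear_slope) || is.null(linear_intercept)) {
    ph <- seq(ph_range[1], ph_range[2], by = 0.05)
    fit <- stats::lm(ratio_from_ph(ph, cal) ~ ph)
    cal$linear_slope <- unname(stats::coef(fit)[2])
    cal$linear_intercept <- unname(stats::coef(fit)[1])
    cal$linear_residual_sd <- stats::sigma(fit)
    cal$r_range <- range(stats::fitted(fit))
  } else {
    cal$r_range <- sort(linear_intercept + linear_slope * ph_range)
  }
  cal
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Ratiometric pH calibration (", x$mode, " mode)\n", sep = "")
  cat(sprintf("  pKa = %.3f, R_A = %.3f, R_B = %.3f, norm_factor = %.3f\n",
              x$pKa, x$R_A, x$R_B, x$norm_factor))
  cat(sprintf("  working range: pH %.2f - %.2f\n", x$ph_range[1], x$ph_range[2]))
  cat(sprintf("  linear fit: R = %.4f %+.4f * pH (residual SD %.2g)\n",
              x$linear_intercept, x$linear_slope, x$linear_residual_sd))
  invisible(x)
}

#' Forward model: emission ratio at a given pH
#'
#' Inverse of [ph_from_ratio()] in ratiometric mode; used by the synthetic
#' renderer and for round-trip validation.
#'
#' @param ph numeric vector of pH values.
#' @param cal a [calibration_model()].
#' @return Emission ratio \eqn{R = F_{600}/F_{667}} at each pH.
#' @export
ratio_from_ph <- function(ph, cal = calibration_model()) {
  q <- 10^(cal$pKa - ph) / cal$norm_factor
  (q * cal$R_A + cal$R_B) / (1 + q)
}

#' Forward model: individual 600/667 nm emission intensities at a given pH
#'
#' Decomposes the probe emission into acid-form and base-form contributions.
#' With the base/acid 667 nm ratio fixed by `norm_factor` and the endpoint
#' ratios by `R_A`, `R_B`, the acid form contributes (R_A, 1) and the base form
#' (R_B * norm_factor, norm_factor) intensity units at (600, 667) nm; the acid
#' fraction follows the Henderson--Hasselbalch equilibrium at `pKa`.
#'
#' @inheritParams ratio_from_ph
#' @param gain multiplicative detector gain applied to both channels.
#' @return A list with numeric vectors `F600` and `F667`.
#' @export
probe_intensities <- function(ph, cal = calibration_model(), gain = 1) {
  f_acid <- 1 / (1 + 10^(ph - cal$pKa))
  list(
    F600 = gain * (f_acid * cal$R_A + (1 - f_acid) * cal$R_B * cal$norm_factor),
    F667 = gain * (f_acid + (1 - f_acid) * cal$norm_factor)
  )
}

#' Emission intensity ratio
#'
#' @param F600,F667 intensities at 600 and 667 nm (background-subtracted).
#' @return `F600 / F667`; frames with `F667 <= 0` yield `NA` and are flagged in
#'   the `"flag"` attribute (`"missing"`) rather than raising an error.
#' @export
intensity_ratio <- function(F600, F667) {
  bad <- !is.finite(F667) | F667 <= 0
  r <- F600 / F667
  r[bad] <- NA_real_
  flag <- ifelse(bad, "missing", "ok")
  attr(r, "flag") <- flag
  r
}

#' Convert emission ratio to pH
#'
#' In `RATIOMETRIC` mode applies the endpoint equation (see
#' [calibration_model()]); in `LINEAR` mode inverts the straight-line fit.
#' Ratios at or beyond the endpoints are saturated (returned as `NA`, flagged
#' `"saturated"`); results outside the working pH range are kept but flagged
#' `"out_of_range"`.
#'
#' @param R numeric vector of emission ratios.
#' @param cal a [calibration_model()].
#' @return Numeric vector of pH values with a `"flag"` character attribute
#'   (`"ok"`, `"saturated"`, `"out_of_range"`, `"missing"`).
#' @export
ph_from_ratio <- function(R, cal = calibration_model()) {
  n <- length(R)
  ph <- rep(NA_real_, n)
  flag <- rep("ok", n)
  miss <- !is.finite(R)
  flag[miss] <- "missing"
  if (cal$mode == "RATIOMETRIC") {
    lo <- min(cal$R_A, cal$R_B); hi <- max(cal$R_A, cal$R_B)
    sat <- !miss & (R <= lo | R >= hi)
    flag[sat] <- "saturated"
    ok <- !miss & !sat
    arg <- (R[ok] - cal$R_B) / (cal$R_A - R[ok]) * cal$norm_factor
    ph[ok] <- cal$pKa - log10(arg)
  } else {
    ok <- !miss
    ph[ok] <- (R[ok] - cal$linear_intercept) / cal$linear_slope
    if (!is.null(cal$r_range)) {
      extr <- ok & (R < cal$r_range[1] | R > cal$r_range[2])
      flag[extr] <- "out_of_range"
    }
  }
  oor <- !is.na(ph) & (ph < cal$ph_range[1] | ph > cal$ph_range[2])
  flag[oor & flag == "ok"] <- "out_of_range"
  attr(ph, "flag") <- flag
  ph
}

#' Fit a straight-line calibration from measured (pH, R) pairs
#'
#' Least-squares fit of emission ratio against buffer pH, as obtained from a
#' buffer titration series. The fitted model refuses silent extrapolation:
#' ratios outside the fitted range are flagged by [ph_from_ratio()].
#'
#' @param ph buffer pH values (at least 3, inside the probe working range).
#' @param R measured emission ratios, same length as `ph`.
#' @param template optional [calibration_model()] whose probe constants are
#'   carried over; defaults to the package default model.
#' @return A `calibration_model` in `LINEAR` mode with `linear_slope`,
#'   `linear_intercept`, residual SD, and the fitted pH/ratio ranges.
#' @export
fit_linear_calibration <- function(ph, R, template = calibration_model()) {
  if (length(ph) != length(R)) stop2("ph and R must have the same length")
  if (length(ph) < 3L) stop2("need at least 3 (pH, R) pairs to fit")
  fit <- stats::lm(R ~ ph)
  cal <- template
  cal$mode <- "LINEAR"
  cal$linear_slope <- unname(stats::coef(fit)[2])
  cal$linear_intercept <- unname(stats::coef(fit)[1])
  cal$linear_residual_sd <- stats::sigma(fit)
  cal$ph_range <- range(ph)
  cal$r_range <- range(R)
  cal$r_squared <- summary(fit)$r.squared
  cal
}
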