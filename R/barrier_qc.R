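#' Blank-corrected transepithelial electrical resistance (TEER)
#'
#' TEER in Ω·cm² is the raw resistance across a cell-covered insert minus the
#' mean resistance of cell-free (blank) inserts, multiplied by the membrane
#' area. A negative corrected value (total below blank) is retained as-is and
#' flagged with a warning rather than clipped, so raw-data audits stay honest.
#'
#' @param total_resistance raw resistance across the insert, in Ω.
#' @param blank_resistance mean resistance of blank inserts, in Ω.
#' @param geometry a [transwell_geometry()], or a membrane area in cm².
#' @return TEER in Ω·cm² (vectorised over resistances).
#' @examples
#' compute_teer(2500, 100, 0.3)   # 720
#' @export
compute_teer <- function(total_resistance, blank_resistance, geometry) {
  area <- if (inherits(geometry, "transwell_geometry"))
    geometry$membrane_area else geometry
  stopifnot(is.numeric(area), length(area) == 1L, area > 0)
  if (any(is.na(blank_resistance)))
    stop("missing blank resistance")
  if (any(is.na(total_resistance)))
    stop("missing total resistance")
  teer <- (total_resistance - blank_resistance) * area
  if (any(teer < 0))
    warning("negative blank-corrected TEER retained (total below blank)")
  teer
}

#' TEER maturation series for one insert
#'
#' @param insert_id insert identifier.
#' @param day days in culture, strictly increasing.
#' @param teer TEER values in Ω·cm².
#' @return An object of class `"teer_series"`.
#' @export
teer_series <- function(insert_id, day, teer) {
  stopifnot(length(day) == length(teer), length(day) >= 1L)
  if (any(diff(day) <= 0)) stop("days must be strictly increasing")
  if (any(!is.finite(teer))) stop("TEER values must be finite")
  structure(list(insert_id = as.character(insert_id),
                 day = as.numeric(day), teer = as.numeric(teer)),
            class = "teer_series")
}

#' Summarise a TEER maturation series
#'
#' Reports the maximum TEER, the day it occurred, and the first day the
#' barrier-tightness threshold was reached.
#'
#' @param series a [teer_series()].
#' @param threshold tightness threshold in Ω·cm² (default 400).
#' @return A list with `max_teer`, `day_of_max`, `first_day_above`
#'   (`NA` when the threshold is never reached) and `days_above`.
#' @examples
#' s <- teer_series("i1", c(35, 40, 45), c(410, 720, 650))
#' summarize_teer(s)
#' @export
summarize_teer <- function(series, threshold = 400) {
  stopifnot(inherits(series, "teer_series"))
  if (length(series$teer) == 0L) stop("empty TEER series")
  i <- which.max(series$teer)
  above <- series$day[series$teer >= threshold]
  list(max_teer = series$teer[i],
       day_of_max = series$day[i],
       first_day_above = if (length(above)) above[1] else NA_real_,
       days_above = above)
}

#' Fit a fluorescence calibration curve
#'
#' Ordinary least-squares line (with intercept) through blank-subtracted
#' fluorescence intensities of sodium-fluorescein standards.
#'
#' @param concentration standard concentrations in nM (at least two distinct).
#' @param intensity blank-subtracted fluorescence intensities.
#' @return An object of class `"calibration_curve"` with `slope`
#'   (intensity per nM), `intercept`, `r_squared` and the standards.
#' @export
fit_calibration <- function(concentration, intensity) {
  stopifnot(is.numeric(concentration), is.numeric(intensity),
            length(concentration) == length(intensity))
  if (length(unique(concentration)) < 2L)
    stop("degenerate design: need at least 2 distinct standard concentrations")
  fit <- stats::lm(intensity ~ concentration)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((intensity - mean(intensity))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    warning("calibration slope is not positive; curve is not usable for inversion")
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 standards = data.frame(concentration = concentration,
                                        intensity = intensity)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration: intensity = %.6g * conc(nM) + %.6g  (R^2 = %.4f, %d standards)\n",
              x$slope, x$intercept, x$r_squared, nrow(x$standards)))
  invisible(x)
}

#' Invert a calibration curve
#'
#' Converts fluorescence intensities to concentrations via
#' `(intensity - intercept) / slope`. Results below the lowest standard are
#' flagged in the `"below_range"` attribute (negative values included).
#'
#' @param curve a [fit_calibration()] result with positive slope.
#' @param intensity intensities to convert.
#' @return Concentrations in nM with a logical `below_range` attribute.
#' @export
intensity_to_concentration <- function(curve, intensity) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(curve$slope) || curve$slope <= 0)
    stop("calibration slope must be > 0")
  conc <- (intensity - curve$intercept) / curve$slope
  attr(conc, "below_range") <- conc < min(curve$standards$concentration)
  conc
}

#' Percentage of tracer transported across the monolayer
#'
#' Leakage is the receiver concentration relative to the donor concentration,
#' corrected for the compartment volume ratio: with an apical donor the
#' receiver is basolateral and the factor is `V_basolateral / V_apical`; with
#' a basolateral donor the factor inverts.
#'
#' @param sample_concentration receiver concentration (same unit as donor).
#' @param donor_concentration donor concentration.
#' @param basolateral_volume,apical_volume compartment volumes in mL.
#' @param donor_side which compartment was dosed.
#' @return Transport percentage.
#' @examples
#' leakage_percent(207.8, 2.66e6, 1, 1)  # 0.0078 % of a 2.66 mM donor
#' @export
leakage_percent <- function(sample_concentration, donor_concentration,
                            basolateral_volume, apical_volume,
                            donor_side = c("apical", "basolateral")) {
  donor_side <- match.arg(donor_side)
  if (!(donor_concentration > 0)) stop("donor concentration must be > 0")
  if (!(basolateral_volume > 0 && apical_volume > 0))
    stop("compartment volumes must be > 0")
  vr <- if (donor_side == "apical") basolateral_volume / apical_volume
        else apical_volume / basolateral_volume
  100 * (sample_concentration / donor_concentration) * vr
}

#' Barrier-integrity gate
#'
#' An insert passes when TEER meets the tightness threshold and tracer
#' leakage stays below the ceiling.
#'
#' @param teer TEER in Ω·cm².
#' @param leakage tracer transport percentage.
#' @param teer_threshold minimum acceptable TEER (default 400 Ω·cm²).
#' @param leakage_ceiling maximum acceptable leakage percentage (default 0.5).
#' @return A list with logical `pass` and a character vector of `reasons`
#'   (empty on pass).
#' @examples
#' assess_barrier(721, 0.021)
#' @export
assess_barrier <- function(teer, leakage, teer_threshold = 400,
                           leakage_ceiling = 0.5) {
  stopifnot(is.numeric(teer), is.numeric(leakage))
  reasons <- character(0)
  if (teer < teer_threshold)
    reasons <- c(reasons, sprintf("TEER %.3g below threshold %.3g Ohm.cm2",
                                  teer, teer_threshold))
  if (leakage > leakage_ceiling)
    reasons <- c(reasons, sprintf("leakage %.3g%% above ceiling %.3g%%",
                                  leakage, leakage_ceiling))
  list(pass = length(reasons) == 0L, reasons = reasons)
}
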