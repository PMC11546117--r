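#' Receiver-compartment concentration time series
#'
#' One insert's measurements from a bidirectional transport experiment: the
#' receiver-compartment concentration (or bioanalytical signal per mL) at
#' each sampling time, the measured dose (donor concentration) in the same
#' unit, the limit of quantification, and the sampling schedule used so that
#' dilution by medium replacement can be corrected for.
#'
#' @param values receiver concentrations/signals per mL at each sampling time.
#' @param times sampling times in hours (default `c(0.5, 1, 1.2, 2)`).
#' @param direction `"A2B"` (apical-to-basolateral) or `"B2A"`.
#' @param donor_value measured dose concentration/signal per mL (same unit as
#'   `values`).
#' @param loq limit of quantification in the same unit (default 5, i.e. 5 nM
#'   for molar data).
#' @param substrate substrate identifier.
#' @param insert_id insert identifier.
#' @param geometry a [transwell_geometry()].
#' @param schedule a [sampling_schedule()]; defaults to half-volume draws at
#'   `times` with replacement except at the terminal sample.
#' @param unit unit tag for `values`, `donor_value` and `loq`
#'   (e.g. `"nM"`, `"signal"`).
#' @param experiment_id experiment (biological replicate) identifier.
#' @return An object of class `"receiver_series"`.
#' @export
receiver_series <- function(values, times = c(0.5, 1, 1.2, 2),
                            direction = c("A2B", "B2A"), donor_value,
                            loq = 5, substrate = "substrate",
                            insert_id = "insert",
                            geometry = transwell_geometry(), schedule = NULL,
                            unit = "nM", experiment_id = "exp1") {
  direction <- match.arg(direction)
  stopifnot(is.numeric(values), is.numeric(times),
            length(values) == length(times), length(times) >= 1L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(values < 0, na.rm = TRUE)) stop("values must be >= 0")
  if (!(loq > 0)) stop("loq must be > 0")
  if (!(donor_value > 0)) stop("donor_value must be > 0")
  side <- if (direction == "A2B") "basolateral" else "apical"
  if (is.null(schedule)) {
    v <- receiver_volume(geometry, direction)
    schedule <- sampling_schedule(times, v / 2)
  }
  schedule <- validate_schedule(schedule, geometry, side)
  if (length(schedule$time) != length(times) ||
      any(abs(schedule$time - times) > 1e-9))
    stop("schedule times do not match series times")
  structure(list(insert_id = as.character(insert_id),
                 experiment_id = as.character(experiment_id),
                 substrate = as.character(substrate),
                 direction = direction, times = as.numeric(times),
                 values = as.numeric(values), loq = loq,
                 donor_value = donor_value, unit = unit,
                 geometry = geometry, schedule = schedule,
                 censored = rep(FALSE, length(values))),
            class = "receiver_series")
}

#' @export
print.receiver_series <- function(x, ...) {
  cat(sprintf("Receiver series %s/%s: %s, %s, donor %.4g %s/mL, LOQ %.3g\n",
              x$experiment_id, x$insert_id, x$substrate, x$direction,
              x$donor_value, x$unit, x$loq))
  print(data.frame(time_h = x$times, value = x$values, censored = x$censored),
        row.names = FALSE)
  invisible(x)
}

#' Flag observations below the limit of quantification
#'
#' Points with `value < loq` are flagged censored; they are excluded from
#' slope fitting but their measured values are retained for the
#' removed-amount bookkeeping. A fully censored series is marked with status
#' `"below_loq"`.
#'
#' @param series a [receiver_series()].
#' @return The series with its `censored` flags set.
#' @export
censor_loq <- function(series) {
  stopifnot(inherits(series, "receiver_series"))
  series$censored <- series$values < series$loq
  if (all(series$censored)) attr(series, "status") <- "below_loq"
  series
}

#' Cumulative amount transported, corrected for sampling dilution
#'
#' Each intermediate draw removes part of the transported amount from the
#' receiver and the replacement medium dilutes what remains, so the cumulative
#' amount transported by time `t_k` is the amount currently in the receiver
#' plus everything removed earlier:
#' `Q(t_k) = C_k * V_receiver + sum_{j<k} C_j * V_removed_j`.
#' Censoring flags carry over point-wise.
#'
#' @param series a [receiver_series()].
#' @return An object of class `"cumulative_transport"` with `times` (h), `q`
#'   (value-unit × mL) and `censored`.
#' @examples
#' s <- receiver_series(c(10, 20, 24, 40), donor_value = 5e4, direction = "A2B")
#' reconstruct_cumulative(s)$q  # 12, 30, 46.8, 80.4 pmol
#' @export
reconstruct_cumulative <- function(series) {
  stopifnot(inherits(series, "receiver_series"))
  v_r <- receiver_volume(series$geometry, series$direction)
  rem <- series$schedule$removed_volume
  n <- length(series$values)
  removed_before <- c(0, cumsum(series$values[-n] * rem[-n]))
  q <- series$values * v_r + removed_before
  structure(list(times = series$times, q = q, censored = series$censored,
                 unit = paste0(series$unit, ".mL"), series = series),
            class = "cumulative_transport")
}

#' Iterative linearity trimming of a cumulative-transport curve
#'
#' Fits an ordinary least-squares line (with intercept) to the uncensored
#' cumulative-transport points, including the implicit origin (0, 0) at dose
#' time. If the coefficient of determination falls short of the linearity
#' threshold, the earliest remaining point is dropped and the fit repeated;
#' only leading points are ever removed. The fit is refused when fewer than
#' `min_points` points remain.
#'
#' @param ct a [reconstruct_cumulative()] result.
#' @param r2_threshold linearity threshold on R² (default 0.970).
#' @param min_points minimum number of fit points (default 3, i.e. more than
#'   2 must remain).
#' @param include_origin include (0, 0) as a fit point (default `TRUE`).
#' @return An object of class `"linear_fit"` with `slope` (amount per s),
#'   `slope_per_h`, `intercept`, `r_squared`, `points_used`, `points_dropped`
#'   and `status` (`"ok"` or `"insufficient_points"`).
#' @export
fit_linear_window <- function(ct, r2_threshold = 0.970, min_points = 3,
                              include_origin = TRUE) {
  stopifnot(inherits(ct, "cumulative_transport"))
  keep <- !ct$censored
  t <- ct$times[keep]
  q <- ct$q[keep]
  if (include_origin) {
    t <- c(0, t)
    q <- c(0, q)
  }
  dropped <- numeric(0)
  repeat {
    if (length(t) < min_points) {
      return(structure(list(slope = NA_real_, slope_per_h = NA_real_,
                            intercept = NA_real_, r_squared = NA_real_,
                            points_used = numeric(0), points_dropped = dropped,
                            status = "insufficient_points"),
                       class = "linear_fit"))
    }
    cf <- stats::coef(stats::lm(q ~ t))
    res <- q - (cf[1] + cf[2] * t)
    ss_tot <- sum((q - mean(q))^2)
    r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
    if (r2 >= r2_threshold) {
      return(structure(list(slope = unname(cf[2]) / 3600,
                            slope_per_h = unname(cf[2]),
                            intercept = unname(cf[1]), r_squared = r2,
                            points_used = t, points_dropped = dropped,
                            status = "ok"),
                       class = "linear_fit"))
    }
    dropped <- c(dropped, t[1])
    t <- t[-1]
    q <- q[-1]
  }
}

#' @export
print.linear_fit <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("Linear fit: %s (dropped: %s)\n", x$status,
                paste(x$points_dropped, collapse = ", ")))
  } else {
    cat(sprintf("Linear fit: slope %.4g/h, R^2 = %.4f, %d points",
                x$slope_per_h, x$r_squared, length(x$points_used)))
    if (length(x$points_dropped))
      cat(sprintf(" (dropped t = %s)", paste(x$points_dropped, collapse = ", ")))
    cat("\n")
  }
  invisible(x)
}

#' Apparent permeability coefficient from a linear fit
#'
#' `Papp = (dQ/dt) / (A * C_donor)` with the slope in amount per second, the
#' membrane area in cm² and the donor concentration per mL; the unit tags of
#' the cumulative amount and the donor value must cancel (both molar or both
#' signal-based).
#'
#' @param fit a [fit_linear_window()] result with status `"ok"`.
#' @param geometry a [transwell_geometry()].
#' @param donor_value donor concentration/signal per mL.
#' @param unit_value,unit_donor unit tags; must match.
#' @return Papp in 10⁻⁶ cm/s.
#' @export
compute_papp <- function(fit, geometry, donor_value,
                         unit_value = "nM", unit_donor = unit_value) {
  stopifnot(inherits(fit, "linear_fit"),
            inherits(geometry, "transwell_geometry"))
  if (!identical(unit_value, unit_donor))
    stop(sprintf("unit mismatch: cumulative amount in %s.mL but donor in %s/mL",
                 unit_value, unit_donor))
  if (!(donor_value > 0)) stop("donor_value must be > 0")
  if (fit$status != "ok") stop("cannot compute Papp from a fit with status ", fit$status)
  papp_cm_s <- fit$slope / (geometry$membrane_area * donor_value)
  if (fit$slope == 0) warning("zero slope: Papp is 0")
  papp_cm_s * 1e6
}

#' Upper bound on Papp for a fully censored series
#'
#' When every receiver sample is below the limit of quantification the
#' permeability cannot be determined, but substituting the LOQ for each
#' sample bounds it from above: the bound is the terminal-time secant slope
#' of the LOQ-substituted cumulative curve divided by area and donor
#' concentration. The bound is linear in the LOQ.
#'
#' @param series a fully censored [receiver_series()].
#' @return Upper-bound Papp in 10⁻⁶ cm/s.
#' @export
loq_bound <- function(series) {
  stopifnot(inherits(series, "receiver_series"))
  series <- censor_loq(series)
  if (!all(series$censored))
    stop("loq_bound requires a fully censored series")
  sub <- series
  sub$values <- rep(series$loq, length(series$values))
  sub$censored <- rep(FALSE, length(series$values))
  ct <- reconstruct_cumulative(sub)
  n <- length(ct$times)
  slope <- ct$q[n] / (ct$times[n] * 3600)  # secant through the origin
  1e6 * slope / (series$geometry$membrane_area * series$donor_value)
}
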