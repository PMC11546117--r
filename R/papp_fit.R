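#' Fit an apparent permeability coefficient to a receiver time series
#'
#' The central estimator of the package. For one insert and direction it
#' (i) censors observations below the limit of quantification,
#' (ii) reconstructs the cumulative amount transported with
#' sampling-dilution correction, (iii) trims leading points until the
#' cumulative curve is linear (R² at or above `r2_threshold`, origin
#' included), and (iv) converts the slope to an apparent permeability
#' `Papp = (dQ/dt) / (A * C_donor)` in 10⁻⁶ cm/s.
#'
#' Outcomes are encoded in `status`:
#' \describe{
#'   \item{`ok`}{a valid fit; `papp` is set.}
#'   \item{`below_loq`}{every sample censored; `papp` is `NA` and `bound`
#'     holds the [loq_bound()] upper bound.}
#'   \item{`two_point_estimate`}{only two measured points survived censoring;
#'     the origin-anchored estimate is reported in `papp` but flagged, since
#'     linearity over measured points cannot be assessed.}
#'   \item{`insufficient_points`}{fewer than `min_points` fit points remain
#'     (before or after trimming); no estimate.}
#' }
#'
#' @param series a [receiver_series()].
#' @param r2_threshold linearity threshold on R² (default 0.970).
#' @param min_points minimum number of fit points, origin included
#'   (default 3).
#' @param include_origin include (0, 0) at dose time as a fit point.
#' @return An object of class `"papp_fit"` with components `papp`
#'   (10⁻⁶ cm/s or `NA`), `status`, `bound`, `fit` (the [fit_linear_window()]
#'   result), `cumulative`, `series`, `direction`, `substrate`.
#' @examples
#' s <- receiver_series(c(10, 20, 24, 40), donor_value = 5e4, direction = "A2B")
#' f <- fit_papp(s)
#' coef(f)
#' @seealso [summarize_direction()], [simulate_transport()]
#' @export
fit_papp <- function(series, r2_threshold = 0.970, min_points = 3,
                     include_origin = TRUE) {
  stopifnot(inherits(series, "receiver_series"))
  series <- censor_loq(series)
  out <- list(papp = NA_real_, status = NA_character_, bound = NULL,
              fit = NULL, cumulative = NULL, series = series,
              direction = series$direction, substrate = series$substrate,
              insert_id = series$insert_id,
              experiment_id = series$experiment_id,
              r2_threshold = r2_threshold, min_points = min_points)
  class(out) <- "papp_fit"
  if (all(series$censored)) {
    out$status <- "below_loq"
    out$bound <- loq_bound(series)
    return(out)
  }
  ct <- reconstruct_cumulative(series)
  out$cumulative <- ct
  fit <- fit_linear_window(ct, r2_threshold = r2_threshold,
                           min_points = min_points,
                           include_origin = include_origin)
  out$fit <- fit
  if (fit$status != "ok") {
    out$status <- fit$status
    return(out)
  }
  out$papp <- compute_papp(fit, series$geometry, series$donor_value,
                           unit_value = series$unit)
  n_measured <- sum(!series$censored)
  out$status <- if (n_measured <= 2) "two_point_estimate" else "ok"
  out
}

#' @export
print.papp_fit <- function(x, ...) {
  cat(sprintf("Apparent permeability fit: %s, %s (%s/%s)\n",
              x$substrate, x$direction, x$experiment_id, x$insert_id))
  if (x$status == "below_loq") {
    cat(sprintf("  all samples below LOQ; Papp <= %.3g x 1e-6 cm/s\n", x$bound))
  } else if (is.na(x$papp)) {
    cat(sprintf("  status: %s (no estimate)\n", x$status))
  } else {
    flag <- if (x$status == "two_point_estimate") " [two-point estimate]" else ""
    cat(sprintf("  Papp = %.3g x 1e-6 cm/s%s\n", x$papp, flag))
    cat(sprintf("  slope %.4g %s/h, R^2 = %.4f, %d fit points, %d dropped, %d censored\n",
                x$fit$slope_per_h, x$cumulative$unit, x$fit$r_squared,
                length(x$fit$points_used), length(x$fit$points_dropped),
                sum(x$series$censored)))
  }
  invisible(x)
}

#' @export
coef.papp_fit <- function(object, ...) {
  c(papp = object$papp,
    slope = if (is.null(object$fit)) NA_real_ else object$fit$slope,
    intercept = if (is.null(object$fit)) NA_real_ else object$fit$intercept)
}

#' @export
summary.papp_fit <- function(object, ...) {
  s <- object$series
  structure(list(substrate = object$substrate, direction = object$direction,
                 experiment_id = object$experiment_id,
                 insert_id = object$insert_id,
                 papp = object$papp, status = object$status,
                 bound = object$bound,
                 r_squared = if (is.null(object$fit)) NA_real_ else object$fit$r_squared,
                 n_censored = sum(s$censored),
                 n_points = length(s$values),
                 points_dropped = if (is.null(object$fit)) numeric(0) else
                   object$fit$points_dropped,
                 donor_value = s$donor_value, unit = s$unit),
            class = "summary.papp_fit")
}

#' @export
print.summary.papp_fit <- function(x, ...) {
  cat(sprintf("%s %s (%s/%s): status %s", x$substrate, x$direction,
              x$experiment_id, x$insert_id, x$status))
  if (!is.na(x$papp)) cat(sprintf(", Papp %.3g x 1e-6 cm/s (R^2 %.4f)",
                                  x$papp, x$r_squared))
  if (!is.null(x$bound)) cat(sprintf(", bound <= %.3g x 1e-6 cm/s", x$bound))
  cat(sprintf("; %d/%d censored\n", x$n_censored, x$n_points))
  invisible(x)
}

#' @export
predict.papp_fit <- function(object, times = NULL, ...) {
  if (is.null(object$fit) || object$fit$status != "ok")
    stop("no valid linear fit to predict from")
  if (is.null(times)) times <- object$cumulative$times
  object$fit$intercept + object$fit$slope_per_h * times
}

#' @export
residuals.papp_fit <- function(object, ...) {
  if (is.null(object$fit) || object$fit$status != "ok")
    stop("no valid linear fit")
  used <- object$fit$points_used
  ct <- object$cumulative
  keep <- !ct$censored & ct$times %in% used
  q <- ct$q[keep]
  t <- ct$times[keep]
  if (0 %in% used) { t <- c(0, t); q <- c(0, q) }
  q - predict(object, t)
}

#' Plot a permeability fit
#'
#' Cumulative amount transported against time, with censored points hollow,
#' trimmed points crossed out and the fitted line over the retained window.
#'
#' @param x a [fit_papp()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.papp_fit <- function(x, ...) {
  if (is.null(x$cumulative)) stop("nothing to plot: series fully censored")
  ct <- x$cumulative
  t <- c(0, ct$times)
  q <- c(0, ct$q)
  cens <- c(FALSE, ct$censored)
  graphics::plot(t, q, xlab = "time (h)",
                 ylab = sprintf("cumulative amount (%s)", ct$unit),
                 main = sprintf("%s %s: Papp fit", x$substrate, x$direction),
                 pch = ifelse(cens, 1, 16), ...)
  if (!is.null(x$fit) && x$fit$status == "ok") {
    used <- x$fit$points_used
    graphics::abline(x$fit$intercept, x$fit$slope_per_h, lty = 2)
    drop <- setdiff(t[!cens], used)
    if (length(drop))
      graphics::points(drop, q[match(drop, t)], pch = 4, cex = 1.5)
  }
  invisible(x)
}
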