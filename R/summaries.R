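#' Directional median permeabilities and polarity ratio
#'
#' Collapses replicate inserts of one substrate within one experiment to a
#' per-direction median Papp and the efflux (polarity) ratio
#' `median(B2A) / median(A2B)`. Only replicates with a valid fit
#' (status `"ok"`) enter the medians. When a direction has no valid fit, the
#' summary carries a qualifier instead: `"<="` with the median LOQ bound when
#' all replicates were fully censored, `"~"` with the flagged value when only
#' a two-point estimate exists, or `NA` when nothing is estimable. The
#' polarity ratio is reported only when both directional medians are valid.
#'
#' @param fits list of [fit_papp()] objects for one substrate and experiment.
#' @param experiment_id experiment identifier (defaults to the fits' common
#'   id).
#' @return An object of class `"directional_summary"`: a list with
#'   `substrate`, `experiment_id`, `median_a2b`, `qual_a2b`, `median_b2a`,
#'   `qual_b2a`, `polarity_ratio`, `n_a2b`, `n_b2a`.
#' @export
summarize_direction <- function(fits, experiment_id = NULL) {
  if (inherits(fits, "papp_fit")) fits <- list(fits)
  stopifnot(is.list(fits), length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "papp_fit")))
  substrate <- unique(vapply(fits, `[[`, character(1), "substrate"))
  if (length(substrate) != 1L)
    stop("all fits must share one substrate")
  if (is.null(experiment_id)) {
    experiment_id <- unique(vapply(fits, `[[`, character(1), "experiment_id"))
    if (length(experiment_id) != 1L)
      stop("all fits must share one experiment")
  }

  one_direction <- function(dir) {
    dfits <- Filter(function(f) f$direction == dir, fits)
    if (!length(dfits))
      return(list(median = NA_real_, qual = NA_character_, n = 0L))
    status <- vapply(dfits, `[[`, character(1), "status")
    ok <- status == "ok"
    if (any(ok)) {
      med <- stats::median(vapply(dfits[ok], `[[`, numeric(1), "papp"))
      return(list(median = med, qual = "", n = length(dfits)))
    }
    if (any(status == "below_loq")) {
      med <- stats::median(vapply(dfits[status == "below_loq"], `[[`,
                                  numeric(1), "bound"))
      return(list(median = med, qual = "<=", n = length(dfits)))
    }
    if (any(status == "two_point_estimate")) {
      med <- stats::median(vapply(dfits[status == "two_point_estimate"], `[[`,
                                  numeric(1), "papp"))
      return(list(median = med, qual = "~", n = length(dfits)))
    }
    list(median = NA_real_, qual = NA_character_, n = length(dfits))
  }

  a2b <- one_direction("A2B")
  b2a <- one_direction("B2A")
  ratio <- if (identical(a2b$qual, "") && identical(b2a$qual, "") &&
               a2b$median > 0) b2a$median / a2b$median else NA_real_
  structure(list(substrate = substrate, experiment_id = experiment_id,
                 median_a2b = a2b$median, qual_a2b = a2b$qual,
                 median_b2a = b2a$median, qual_b2a = b2a$qual,
                 polarity_ratio = ratio,
                 n_a2b = a2b$n, n_b2a = b2a$n),
            class = "directional_summary")
}

#' @export
print.directional_summary <- function(x, ...) {
  fmt <- function(m, q) {
    if (is.na(m)) return("--")
    paste0(if (nzchar(q %||% "")) paste0(q, " ") else "", sprintf("%.3g", m))
  }
  cat(sprintf("%s (%s): A2B %s, B2A %s (x 1e-6 cm/s)",
              x$substrate, x$experiment_id,
              fmt(x$median_a2b, x$qual_a2b), fmt(x$median_b2a, x$qual_b2a)))
  if (!is.na(x$polarity_ratio))
    cat(sprintf(", polarity B2A/A2B = %.3g", x$polarity_ratio))
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) {
  if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
}

#' Fold-range of quantifiable median permeabilities
#'
#' Ratio of the largest to the smallest quantifiable median Papp across
#' substrates, directions and experiments. Bounds (`<=`), flagged estimates
#' and undetermined entries are excluded.
#'
#' @param summaries list of [summarize_direction()] objects, or a data frame
#'   with columns `median` and `qual` (as from [read_papp_medians()]), or a
#'   plain numeric vector of quantifiable medians.
#' @return The fold-range (max/min).
#' @export
dynamic_range <- function(summaries) {
  vals <- if (is.numeric(summaries)) {
    summaries
  } else if (is.data.frame(summaries)) {
    summaries$median[!is.na(summaries$median) & summaries$qual == ""]
  } else {
    unlist(lapply(summaries, function(s) {
      stopifnot(inherits(s, "directional_summary"))
      c(if (identical(s$qual_a2b, "")) s$median_a2b,
        if (identical(s$qual_b2a, "")) s$median_b2a)
    }))
  }
  vals <- vals[is.finite(vals) & vals > 0]
  if (length(vals) < 2L)
    stop("need at least 2 quantifiable median permeabilities")
  max(vals) / min(vals)
}

#' Assemble a permeability summary table
#'
#' One row per substrate × direction × experiment, in the layout used to
#' report bidirectional screens: the median Papp with a footnote code —
#' `"a"` not determinable, `"b"` estimated from two time points, `"c"` below
#' the quantification limit (value is the upper bound).
#'
#' @param summaries list of [summarize_direction()] objects.
#' @return A data frame with columns `substrate`, `direction`, `experiment`,
#'   `median_papp`, `code`.
#' @export
papp_table <- function(summaries) {
  stopifnot(is.list(summaries), length(summaries) >= 1L)
  rows <- lapply(summaries, function(s) {
    code <- function(q) {
      if (is.null(q) || is.na(q)) "a"
      else if (q == "<=") "c"
      else if (q == "~") "b"
      else ""
    }
    data.frame(
      substrate = rep(s$substrate, 2L),
      direction = c("A2B", "B2A"),
      experiment = rep(s$experiment_id, 2L),
      median_papp = c(s$median_a2b, s$median_b2a),
      code = c(code(s$qual_a2b), code(s$qual_b2a)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$substrate, out$direction, out$experiment), , drop = FALSE]
}

#' Write a permeability summary table to CSV
#'
#' @param summaries list of [summarize_direction()] objects or a data frame
#'   from [papp_table()].
#' @param path output file path.
#' @return The table, invisibly.
#' @export
write_papp_table <- function(summaries, path) {
  tab <- if (is.data.frame(summaries)) summaries else papp_table(summaries)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(tab)
}

#' Published median permeabilities of the mammary barrier probe panel
#'
#' Reads the packaged reference table of median apparent permeabilities
#' (10⁻⁶ cm/s) of seven probe substrates measured bidirectionally across a
#' primary human mammary epithelial cell monolayer in three independent
#' experiments. Footnote codes: `"a"` not determinable, `"b"` estimated from
#' two time points, `"c"` upper bound (samples below the quantification
#' limit). The `qual` column translates the codes for [dynamic_range()].
#'
#' @param path CSV path; defaults to the copy shipped with the package.
#' @return A data frame with columns `substrate`, `direction`, `experiment`,
#'   `median`, `code`, `qual`.
#' @export
read_papp_medians <- function(path = system.file("extdata",
                                                 "hmec_papp_medians.csv",
                                                 package = "milkbarrier")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$code[is.na(df$code)] <- ""
  df$qual <- c(a = NA_character_, b = "~", c = "<=")[df$code]
  df$qual[df$code == ""] <- ""
  df
}
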