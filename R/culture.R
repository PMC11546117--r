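#' Population doubling time from a pair of cell counts
#'
#' Assumes exponential growth: `DT = (t1 - t0) * ln 2 / ln(n1 / n0)`.
#' A shrinking population gives a negative doubling time (flagged with a
#' warning); equal counts give an infinite doubling time.
#'
#' @param n0,n1 cell counts at the start and end of the interval.
#' @param t1 end time in hours.
#' @param t0 start time in hours (default 0).
#' @return Doubling time in hours (vectorised).
#' @examples
#' doubling_time(1e5, 2e5, 36.6)       # 36.6
#' doubling_time(1e5, 3e5, 48)         # 48 * log(2) / log(3)
#' @export
doubling_time <- function(n0, n1, t1, t0 = 0) {
  stopifnot(is.numeric(n0), is.numeric(n1), is.numeric(t1), is.numeric(t0))
  if (any(n0 <= 0) || any(n1 <= 0)) stop("cell counts must be > 0")
  if (any(t1 <= t0)) stop("t1 must exceed t0")
  dt <- (t1 - t0) * log(2) / log(n1 / n0)
  if (any(is.infinite(dt)))
    warning("equal counts: doubling time is infinite")
  if (any(dt < 0))
    warning("population shrank over the interval: negative doubling time")
  dt
}

#' Read a cell-count table
#'
#' Expects columns `flask_id`, `t_h`, `count`.
#'
#' @param path CSV path.
#' @return A data frame suitable for [summarize_doubling_time()].
#' @export
read_growth_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("flask_id", "t_h", "count")
  if (!all(need %in% names(df)))
    stop("growth table must have columns: ", paste(need, collapse = ", "))
  df[need]
}

#' Summarise doubling times over flasks
#'
#' Two groupings are reported, since replicate structure varies between labs:
#' per flask, the doubling time from a log-linear regression of count on time
#' over all of that flask's observations; and per consecutive interval, the
#' two-point [doubling_time()]. Each grouping gets a mean and SD.
#'
#' @param counts data frame with columns `flask_id`, `t_h`, `count`.
#' @return A list with `per_flask` and `per_interval` data frames and
#'   `mean_h` / `sd_h` for each grouping.
#' @export
summarize_doubling_time <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("flask_id", "t_h", "count") %in% names(counts)))
  flasks <- split(counts, counts$flask_id)
  per_flask <- do.call(rbind, lapply(flasks, function(f) {
    f <- f[order(f$t_h), ]
    if (nrow(f) < 2) return(NULL)
    slope <- unname(stats::coef(stats::lm(log(count) ~ t_h, data = f))[2])
    data.frame(flask_id = f$flask_id[1], doubling_time_h = log(2) / slope)
  }))
  per_interval <- do.call(rbind, lapply(flasks, function(f) {
    f <- f[order(f$t_h), ]
    if (nrow(f) < 2) return(NULL)
    i <- seq_len(nrow(f) - 1)
    data.frame(flask_id = f$flask_id[1], t0 = f$t_h[i], t1 = f$t_h[i + 1],
               doubling_time_h = doubling_time(f$count[i], f$count[i + 1],
                                               f$t_h[i + 1], f$t_h[i]))
  }))
  rownames(per_flask) <- rownames(per_interval) <- NULL
  list(per_flask = per_flask,
       per_interval = per_interval,
       flask_mean_h = mean(per_flask$doubling_time_h),
       flask_sd_h = stats::sd(per_flask$doubling_time_h),
       interval_mean_h = mean(per_interval$doubling_time_h),
       interval_sd_h = stats::sd(per_interval$doubling_time_h))
}
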