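#' Read a transwell resistance table
#'
#' Expects columns `insert_id`, `day`, `total_ohm`, `is_blank`. Blank-insert
#' rows define the blank resistance: the mean over blanks measured the same
#' day, falling back to the mean over all blanks when a day has none. Returns
#' blank-corrected TEER per cell-covered insert and day.
#'
#' @param path CSV path.
#' @param geometry a [transwell_geometry()] providing the membrane area.
#' @return A data frame with columns `insert_id`, `day`, `total_ohm`,
#'   `blank_ohm`, `teer`.
#' @export
read_teer_csv <- function(path, geometry = transwell_geometry()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("insert_id", "day", "total_ohm", "is_blank")
  if (!all(need %in% names(df)))
    stop("resistance table must have columns: ", paste(need, collapse = ", "))
  df$is_blank <- as.logical(df$is_blank)
  blanks <- df[df$is_blank, ]
  if (nrow(blanks) == 0L) stop("missing blank: no blank-insert rows present")
  global_blank <- mean(blanks$total_ohm)
  per_day <- tapply(blanks$total_ohm, blanks$day, mean)
  cells <- df[!df$is_blank, c("insert_id", "day", "total_ohm")]
  blank_ohm <- per_day[as.character(cells$day)]
  blank_ohm[is.na(blank_ohm)] <- global_blank
  cells$blank_ohm <- as.numeric(blank_ohm)
  cells$teer <- compute_teer(cells$total_ohm, cells$blank_ohm, geometry)
  rownames(cells) <- NULL
  cells
}

#' Read a fluorescence plate table
#'
#' Expects columns `well`, `role` (one of `standard`, `sample`, `blank`),
#' `conc_nM` (standards only) and `intensity`. The mean blank intensity is
#' subtracted from standards and samples.
#'
#' @param path CSV path.
#' @return A list with `standards` (data frame `concentration`, `intensity`,
#'   blank-subtracted), `samples` (data frame `well`, `intensity`) and
#'   `blank_intensity`.
#' @export
read_fluorescence_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "role", "intensity")
  if (!all(need %in% names(df)))
    stop("fluorescence table must have columns: ", paste(need, collapse = ", "))
  blank <- mean(df$intensity[df$role == "blank"])
  if (is.nan(blank)) blank <- 0
  std <- df[df$role == "standard", ]
  smp <- df[df$role == "sample", ]
  list(standards = data.frame(concentration = std$conc_nM,
                              intensity = std$intensity - blank),
       samples = data.frame(well = smp$well,
                            intensity = smp$intensity - blank),
       blank_intensity = blank)
}

#' Read bidirectional transport data
#'
#' Expects long-format columns `insert_id`, `substrate`, `direction`
#' (`A2B`/`B2A`), `time_h`, `value`, `unit`, `donor_value`, `loq`, and
#' optionally `experiment_id`. Rows are grouped per insert × substrate ×
#' direction into [receiver_series()] objects with the default half-volume
#' sampling schedule at the observed times.
#'
#' @param path CSV path.
#' @param geometry a [transwell_geometry()].
#' @return A list of [receiver_series()].
#' @export
read_transport_csv <- function(path, geometry = transwell_geometry()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("insert_id", "substrate", "direction", "time_h", "value",
            "unit", "donor_value", "loq")
  if (!all(need %in% names(df)))
    stop("transport table must have columns: ", paste(need, collapse = ", "))
  if (is.null(df$experiment_id)) df$experiment_id <- "exp1"
  key <- interaction(df$experiment_id, df$insert_id, df$substrate,
                     df$direction, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$time_h), ]
    receiver_series(values = g$value, times = g$time_h,
                    direction = g$direction[1],
                    donor_value = g$donor_value[1], loq = g$loq[1],
                    substrate = g$substrate[1], insert_id = g$insert_id[1],
                    geometry = geometry, unit = g$unit[1],
                    experiment_id = g$experiment_id[1])
  })
}

#' Read a qPCR Ct table
#'
#' Expects columns `replicate`, `gene`, `ct`. Array software encodes an
#' undetermined Ct in several ways; all are accepted: an empty cell, a
#' non-numeric marker (e.g. `"Undetermined"` or `">35"`), or a sentinel
#' cycle number (`undetermined_ct`, default 40). All become `NA`.
#'
#' @param path CSV path.
#' @param undetermined_ct sentinel Ct value treated as undetermined; set to
#'   `NULL` to keep numeric values as measured.
#' @return A data frame with columns `replicate`, `gene`, `ct`.
#' @export
read_ct_csv <- function(path, undetermined_ct = 40) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(ct = "character"))
  need <- c("replicate", "gene", "ct")
  if (!all(need %in% names(df)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  ct <- suppressWarnings(as.numeric(df$ct))  # blanks and markers -> NA
  if (!is.null(undetermined_ct))
    ct[!is.na(ct) & ct >= undetermined_ct] <- NA_real_
  df$ct <- ct
  df[need]
}

#' Read a pipeline configuration file
#'
#' A single YAML file declares the insert geometry, sampling times, donor
#' concentration, limit of quantification and QC thresholds consumed by all
#' pipeline stages. Missing keys fall back to the package defaults (the
#' standard mammary-barrier study design).
#'
#' @param path YAML config path.
#' @return A list with `geometry` (a [transwell_geometry()]), `times`,
#'   `donor_concentration`, `loq`, `teer_threshold`, `leakage_ceiling`,
#'   `r2_threshold`, `min_points`, `seed`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  gargs <- raw$geometry %||% list()
  geometry <- do.call(transwell_geometry, gargs)
  list(geometry = geometry,
       times = raw$times %||% c(0.5, 1, 1.2, 2),
       donor_concentration = raw$donor_concentration %||% 50,
       loq = raw$loq %||% 5,
       teer_threshold = raw$teer_threshold %||% 400,
       leakage_ceiling = raw$leakage_ceiling %||% 0.5,
       r2_threshold = raw$r2_threshold %||% 0.970,
       min_points = raw$min_points %||% 3,
       seed = raw$seed %||% 1L)
}

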