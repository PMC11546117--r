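#' Reference-gene panel for relative expression
#'
#' The default panel is the five housekeeping genes of the human drug
#' transporter qPCR array: ACTB, B2M, GAPDH, HPR1 and RPLP0.
#'
#' @param genes character vector of reference-gene identifiers.
#' @return An object of class `"reference_panel"`.
#' @export
reference_panel <- function(genes = c("ACTB", "B2M", "GAPDH", "HPR1", "RPLP0")) {
  stopifnot(is.character(genes), length(genes) >= 1L, !anyDuplicated(genes))
  structure(list(genes = genes), class = "reference_panel")
}

#' Relative expression by the delta-Ct method
#'
#' For each replicate, `deltaCt(gene) = mean(Ct over reference genes) -
#' Ct(gene)`; larger (less negative) values mean higher expression. Per-gene
#' results are the mean and standard deviation of the replicate deltaCt
#' values. A Ct that is missing or above the detectability ceiling counts as
#' undetermined in that replicate; a gene is detectable when it is determined
#' in at least `min_detected` replicates (default: all of them).
#'
#' @param records data frame with columns `replicate`, `gene`, `ct`
#'   (`NA` = undetermined).
#' @param panel a [reference_panel()]; its genes must be determined in every
#'   replicate and are excluded from the results.
#' @param max_ct detectability ceiling: Ct values above this cycle are
#'   treated as undetermined (default 35).
#' @param min_detected minimum number of determined replicates for a gene to
#'   count as detectable; `NULL` (default) requires all replicates.
#' @return A data frame of class `"delta_ct_result"` with one row per target
#'   gene: `gene`, `delta_ct`, `sd`, `n_detected`, `n_replicates`,
#'   `detectable`.
#' @examples
#' ct <- data.frame(replicate = "r1",
#'                  gene = c("ACTB", "B2M", "GAPDH", "HPR1", "RPLP0", "ABCB1"),
#'                  ct = c(20, 20, 20, 20, 20, 25))
#' compute_delta_ct(ct)  # ABCB1: delta Ct = -5
#' @export
compute_delta_ct <- function(records, panel = reference_panel(), max_ct = 35,
                             min_detected = NULL) {
  stopifnot(is.data.frame(records),
            all(c("replicate", "gene", "ct") %in% names(records)),
            inherits(panel, "reference_panel"))
  records$ct[!is.na(records$ct) & records$ct > max_ct] <- NA_real_
  reps <- unique(records$replicate)
  targets <- setdiff(unique(records$gene), panel$genes)

  per_rep <- lapply(reps, function(r) {
    sub <- records[records$replicate == r, ]
    ref <- sub$ct[match(panel$genes, sub$gene)]
    if (anyNA(ref))
      stop(sprintf("replicate %s is missing a determined Ct for reference gene(s): %s",
                   r, paste(panel$genes[is.na(ref)], collapse = ", ")))
    ref_mean <- mean(ref)
    ct <- sub$ct[match(targets, sub$gene)]
    ref_mean - ct  # NA stays NA for undetermined targets
  })
  mat <- do.call(cbind, per_rep)  # genes x replicates
  n_det <- rowSums(!is.na(mat))
  need <- if (is.null(min_detected)) length(reps) else min_detected
  out <- data.frame(
    gene = targets,
    delta_ct = ifelse(n_det > 0, rowMeans(mat, na.rm = TRUE), NA_real_),
    sd = apply(mat, 1, function(x) if (sum(!is.na(x)) > 1) stats::sd(x, na.rm = TRUE) else NA_real_),
    n_detected = n_det,
    n_replicates = length(reps),
    detectable = n_det >= need,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("delta_ct_result", "data.frame")
  out
}

#' Count detectable and undetectable genes
#'
#' @param results a [compute_delta_ct()] result.
#' @return A list with `n_detectable`, `n_undetectable` and
#'   `undetectable_genes`.
#' @export
detectability_summary <- function(results) {
  stopifnot(is.data.frame(results), "detectable" %in% names(results))
  und <- results$gene[!results$detectable]
  list(n_detectable = sum(results$detectable),
       n_undetectable = length(und),
       undetectable_genes = und)
}

#' Write a ranked delta-Ct table
#'
#' Genes sorted by decreasing relative expression, undetectable genes last.
#'
#' @param results a [compute_delta_ct()] result.
#' @param path output CSV path.
#' @return The sorted table, invisibly.
#' @export
write_delta_ct_table <- function(results, path) {
  ord <- order(!results$detectable, -ifelse(is.na(results$delta_ct), -Inf,
                                            results$delta_ct))
  out <- results[ord, , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(out)
}
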