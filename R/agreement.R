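#' Summarize agreement records
#'
#' Collapses per-lesion agreement records into the study's summary surface:
#' per comparison (optionally stratified by a lesion covariate) the number of
#' lesions, median / quartiles / range of HD95, and the count and percentage
#' of lesions exceeding the clinical threshold. Quartiles use the same linear
#' interpolation between order statistics as the HD95 percentile itself.
#'
#' @param records agreement records (see [evaluate_agreement()]).
#' @param meta optional per-lesion metadata, required when `stratify_by` is
#'   given.
#' @param stratify_by optional `meta` column to stratify by (e.g.
#'   `"pigmentation"`); `NULL` summarizes each comparison overall.
#' @param threshold_mm clinical threshold, mm.
#' @param comparator `">"` (strict, the acceptability statement) or `">="`
#'   (inclusive, the stratified-count convention).
#' @param value which metric column to summarize (default `"hd95_mm"`).
#' @return a data.frame with one row per comparison (x stratum): `n`,
#'   `median_mm`, `q1_mm`, `q3_mm`, `min_mm`, `max_mm`, `n_exceeding`,
#'   `pct_exceeding`.
#' @export
summarize_agreement <- function(records, meta = NULL, stratify_by = NULL,
                                threshold_mm = 2.0, comparator = ">",
                                value = "hd95_mm") {
  records <- as.data.frame(records)
  comparator <- match.arg(comparator, c(">", ">="))
  if (!is.null(stratify_by)) {
    if (is.null(meta)) stop("stratification requires lesion metadata")
    if (!stratify_by %in% names(meta))
      stop("unknown stratification column: ", stratify_by)
    records <- merge(records, meta[, c("lesion_id", stratify_by)],
                     by = "lesion_id", sort = TRUE)
    records$.stratum <- as.character(records[[stratify_by]])
  } else {
    records$.stratum <- "overall"
  }
  exceed_fun <- if (comparator == ">") `>` else `>=`
  groups <- split(records,
                  list(records$comparison, records$.stratum), drop = TRUE)
  rows <- lapply(groups, function(g) {
    v <- g[[value]]
    if (length(v) == 0L) return(NULL)
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    nx <- sum(exceed_fun(v, threshold_mm))
    data.frame(comparison = g$comparison[1L], stratum = g$.stratum[1L],
               n = length(v), median_mm = q[2L], q1_mm = q[1L],
               q3_mm = q[3L], min_mm = min(v), max_mm = max(v),
               n_exceeding = nx, pct_exceeding = 100 * nx / length(v))
  })
  empty <- vapply(rows, is.null, logical(1))
  if (any(empty)) warning("empty group(s) omitted from summary")
  out <- do.call(rbind, rows[!empty])
  rownames(out) <- NULL
  out[order(out$comparison, out$stratum), , drop = FALSE]
}

#' Threshold exceedance table
#'
#' Per stratum and comparison, the count of lesions whose HD95 meets the
#' threshold criterion, as `n_exceeding / n` with percentage and a formatted
#' `"k of n (p%)"` label. The default comparator is inclusive (`>=`),
#' matching the convention of stratified suboptimal-agreement counts; the
#' strict comparator matches the overall acceptability statement.
#'
#' @param records agreement records.
#' @param meta per-lesion metadata containing `stratify_by`.
#' @param threshold_mm threshold, mm.
#' @param comparator `">="` (default) or `">"`.
#' @param stratify_by `meta` column defining strata (default
#'   `"pigmentation"`; categories are validated).
#' @return a data.frame with `stratum`, `comparison`, `n`, `n_exceeding`,
#'   `pct_exceeding`, `label`.
#' @export
threshold_table <- function(records, meta, threshold_mm = 2.0,
                            comparator = ">=", stratify_by = "pigmentation") {
  records <- as.data.frame(records)
  comparator <- match.arg(comparator, c(">=", ">"))
  if (!stratify_by %in% names(meta))
    stop("unknown stratification column: ", stratify_by)
  if (stratify_by == "pigmentation") {
    bad <- setdiff(unique(as.character(meta$pigmentation)), PIGMENTATION_LEVELS)
    if (length(bad))
      stop("unknown pigmentation category: ", paste(bad, collapse = ", "))
  }
  df <- merge(records, meta[, c("lesion_id", stratify_by)],
              by = "lesion_id", sort = TRUE)
  df$.stratum <- as.character(df[[stratify_by]])
  exceed_fun <- if (comparator == ">") `>` else `>=`
  groups <- split(df, list(df$.stratum, df$comparison), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    nx <- sum(exceed_fun(g$hd95_mm, threshold_mm))
    n <- nrow(g)
    data.frame(stratum = g$.stratum[1L], comparison = g$comparison[1L],
               n = n, n_exceeding = nx, pct_exceeding = 100 * nx / n,
               label = sprintf("%d of %d (%.1f%%)", nx, n, 100 * nx / n))
  }))
  rownames(out) <- NULL
  out[order(out$comparison, out$stratum), , drop = FALSE]
}
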