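#' Coregister a cohort's annotations into the reference frame
#'
#' For every lesion, estimates the similarity transform of each unimodal
#' pixel frame from the landmarks shared with the reference (multimodal)
#' landmark set, then maps the pixel-frame annotations through it. This is
#' the estimation counterpart of the generator's true transforms; with
#' noiseless landmarks the transforms are recovered exactly.
#'
#' @param cohort a `"synthetic_cohort"` (or any list with the same lesion
#'   structure: `annotations`, `landmarks` per lesion).
#' @return the cohort with, per lesion, `registered` (annotations in the
#'   reference frame) and `est_transforms` (fitted
#'   `"similarity_transform"`s, with landmark `rmse_mm`).
#' @export
register_cohort <- function(cohort) {
  for (i in seq_along(cohort$lesions)) {
    l <- cohort$lesions[[i]]
    mods <- setdiff(names(l$landmarks), "MULTI")
    est <- lapply(setNames(mods, mods), function(mod)
      estimate_transform(l$landmarks[[mod]], l$landmarks[["MULTI"]]))
    registered <- lapply(l$annotations, function(a) {
      mod <- a$modality
      apply_transform(a, est[[mod]])
    })
    cohort$lesions[[i]]$est_transforms <- est
    cohort$lesions[[i]]$registered <- registered
  }
  cohort
}

COMPARISON_PAIRS <- list(
  g1_CFP_vs_multi = c("grader1.CFP", "consensus"),
  g1_SLO_vs_multi = c("grader1.SLO", "consensus"),
  g2_CFP_vs_multi = c("grader2.CFP", "consensus"),
  g2_SLO_vs_multi = c("grader2.SLO", "consensus"),
  g1_vs_g2_CFP    = c("grader1.CFP", "grader2.CFP"),
  g1_vs_g2_SLO    = c("grader1.SLO", "grader2.SLO"))

#' Compute agreement records for a registered cohort
#'
#' Per lesion: intersects the per-modality fields of view into the largest
#' common region, crops every annotation (and the consensus) to it, and
#' computes HD95, the full Hausdorff distance, and optionally Dice for each
#' requested comparison pair. Lesions whose contours disappear under
#' cropping are excluded from the affected comparison with a warning.
#'
#' @param cohort a registered cohort (see [register_cohort()]).
#' @param config a [pipeline_config()] supplying percentile, HD95 method,
#'   densification spacing, crop-edge policy, and threshold.
#' @param comparisons subset of comparison labels to compute (default: all
#'   six grader/modality pairs).
#' @param with_dice compute Dice as well (disable for large simulation runs
#'   where only HD95 is consumed).
#' @return a data.frame of agreement records: `lesion_id`, `comparison`,
#'   `hd95_mm`, `hausdorff_mm`, `dice`, `exceeds_2mm` (strict `>` against
#'   `config$threshold_mm`).
#' @export
evaluate_agreement <- function(cohort, config = pipeline_config(),
                               comparisons = names(COMPARISON_PAIRS),
                               with_dice = TRUE) {
  comparisons <- match.arg(comparisons, names(COMPARISON_PAIRS),
                           several.ok = TRUE)
  rows <- vector("list", length(cohort$lesions) * length(comparisons))
  k <- 0L
  for (l in cohort$lesions) {
    if (is.null(l$registered))
      stop("cohort is not registered; call register_cohort() first")
    rect <- common_region(l$fovs)
    pool <- c(l$registered, list(consensus = l$consensus))
    needed <- unique(unlist(COMPARISON_PAIRS[comparisons]))
    cropped <- list()
    for (nm in needed) {
      cropped[[nm]] <- tryCatch(crop_contour(pool[[nm]], rect)$cropped,
                                error = function(e) {
                                  warning("lesion ", l$lesion_id, " (", nm,
                                          "): ", conditionMessage(e))
                                  NULL
                                })
    }
    for (cmp in comparisons) {
      pair <- COMPARISON_PAIRS[[cmp]]
      a <- cropped[[pair[1L]]]; b <- cropped[[pair[2L]]]
      if (is.null(a) || is.null(b)) next
      m <- pair_metrics(a, b, percentile = config$percentile,
                        method = config$hd95_method,
                        spacing_mm = config$densify_spacing_mm,
                        edge_policy = config$crop_edge_policy,
                        crop_rect = rect,
                        threshold_mm = config$threshold_mm,
                        with_dice = with_dice)
      k <- k + 1L
      rows[[k]] <- data.frame(lesion_id = l$lesion_id, comparison = cmp,
                              hd95_mm = m$hd95_mm,
                              hausdorff_mm = m$hausdorff_mm,
                              dice = m$dice, exceeds_2mm = m$exceeds)
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Run a complete simulated border-agreement study
#'
#' End-to-end pipeline: generate a synthetic cohort, coregister the
#' pixel-frame annotations via landmarks, crop to the common field of view,
#' compute agreement metrics, and produce the study's summary and inferential
#' surfaces (per-comparison summaries, threshold exceedance tables, paired
#' Wilcoxon comparisons, and univariable patient-clustered Gaussian GEE
#' models for pigmentation).
#'
#' @param config a [pipeline_config()]; `config$seed` (if set) seeds the
#'   generator.
#' @param gee_predictors `meta` columns modelled by GEE.
#' @param with_dice compute Dice in the record table.
#' @return an object of class `"border_study"`: `cohort`, `records`,
#'   `summary`, `summary_by_pigmentation`, `threshold_table`, `wilcoxon`,
#'   `gee`, and the `config`.
#' @export
run_study <- function(config = pipeline_config(),
                      gee_predictors = "pigmentation", with_dice = TRUE) {
  if (!is.null(config$seed)) config$cohort$seed <- config$seed
  cohort <- generate_cohort(config$cohort)
  cohort <- register_cohort(cohort)
  records <- evaluate_agreement(cohort, config, with_dice = with_dice)
  summary_all <- summarize_agreement(records,
                                     threshold_mm = config$threshold_mm,
                                     comparator = ">")
  summary_pig <- summarize_agreement(records, cohort$meta,
                                     stratify_by = "pigmentation",
                                     threshold_mm = config$threshold_mm,
                                     comparator = ">=")
  thr <- threshold_table(records, cohort$meta,
                         threshold_mm = config$threshold_mm,
                         comparator = ">=")
  wx <- wilcoxon_comparisons(records)
  gee <- run_gee_models(records, cohort$meta, predictors = gee_predictors)
  structure(list(config = config, cohort = cohort, records = records,
                 summary = summary_all, summary_by_pigmentation = summary_pig,
                 threshold_table = thr, wilcoxon = wx, gee = gee),
            class = "border_study")
}

#' @export
print.border_study <- function(x, ...) {
  cat(sprintf("Simulated border-agreement study: %d lesions / %d patients (seed %s)\n\n",
              x$config$cohort$n_lesions, x$config$cohort$n_patients,
              format(x$config$cohort$seed)))
  cat(sprintf("HD95 by comparison (threshold %.1f mm, strict >):\n",
              x$config$threshold_mm))
  s <- x$summary
  s[, sapply(s, is.numeric)] <- round(s[, sapply(s, is.numeric)], 3)
  print(s, row.names = FALSE)
  cat("\nWilcoxon signed-rank comparisons:\n")
  print(transform(x$wilcoxon, p_value = signif(p_value, 3)),
        row.names = FALSE)
  cat("\nGEE delta-mean HD95 (vs pigmented reference):\n")
  g <- x$gee[, c("comparison", "level", "estimate", "robust_se", "p_value",
                 "joint_p")]
  g[, 3:6] <- signif(g[, 3:6], 3)
  print(g, row.names = FALSE)
  invisible(x)
}
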