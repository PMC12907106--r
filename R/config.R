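#' Default pipeline configuration
#'
#' Bundles the tunable parameters of the agreement pipeline with their
#' defaults: the 2 mm clinical acceptability threshold, the 95th percentile,
#' the pooled HD95 variant, a 0.01 mm densification spacing (two orders of
#' magnitude below the clinical threshold), and the crop-edge policy
#' `"include"` (boundary points created by cropping participate in the
#' metric). The `cohort` element holds the synthetic-cohort generator
#' configuration (see [cohort_config()]).
#'
#' @param threshold_mm clinical acceptability threshold, mm (> 0).
#' @param percentile percentile of the pooled distance distribution, in
#'   (0, 100].
#' @param hd95_method `"pooled"` (symmetric, default) or `"max_directed"`.
#' @param densify_spacing_mm boundary densification spacing, mm (> 0).
#' @param crop_edge_policy `"include"` or `"exclude"`.
#' @param seed integer seed driving every random draw, or `NULL`.
#' @param cohort a list of [cohort_config()] overrides (or a full config).
#' @return a validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(threshold_mm = 2.0, percentile = 95,
                            hd95_method = "pooled",
                            densify_spacing_mm = 0.01,
                            crop_edge_policy = "include", seed = NULL,
                            cohort = list()) {
  cfg <- structure(
    list(threshold_mm = threshold_mm, percentile = percentile,
         hd95_method = hd95_method,
         densify_spacing_mm = densify_spacing_mm,
         crop_edge_policy = crop_edge_policy, seed = seed,
         cohort = do.call(cohort_config, as.list(cohort))),
    class = "pipeline_config")
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  with(cfg, {
    if (!(is.numeric(threshold_mm) && threshold_mm > 0))
      stop("threshold_mm must be a positive number")
    if (!(is.numeric(percentile) && percentile > 0 && percentile <= 100))
      stop("percentile must be in (0, 100]")
    if (!hd95_method %in% c("pooled", "max_directed"))
      stop("hd95_method must be 'pooled' or 'max_directed'")
    if (!(is.numeric(densify_spacing_mm) && densify_spacing_mm > 0))
      stop("densify_spacing_mm must be positive")
    if (!crop_edge_policy %in% c("include", "exclude"))
      stop("crop_edge_policy must be 'include' or 'exclude'")
    if (!is.null(seed) && !(is.numeric(seed) && seed == round(seed)))
      stop("seed must be an integer or NULL")
  })
  cfg
}

#' Load a pipeline configuration file
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON configuration, applies the package
#' defaults for any key not given, and rejects unknown keys rather than
#' silently ignoring them. An empty file yields the full default
#' configuration.
#'
#' @param path path to a YAML or JSON file, or `NULL` for pure defaults.
#' @return a validated `"pipeline_config"`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(pipeline_config())
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (is.null(raw)) raw <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$cohort)) {
    known_cohort <- names(formals(cohort_config))
    unknown <- setdiff(names(raw$cohort), known_cohort)
    if (length(unknown))
      stop("unknown cohort configuration key(s): ",
           paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}
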