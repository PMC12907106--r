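#' Read contour annotations from GeoJSON
#'
#' Contours are interchanged as a GeoJSON FeatureCollection with one Polygon
#' (or MultiPolygon, for cropped multi-part borders) feature per annotation
#' and properties `lesion_id`, `grader`, `modality`, `frame`. Rings are
#' cleaned (consecutive duplicates and the explicit closing vertex removed)
#' and normalized to counter-clockwise orientation on read.
#'
#' @param path path to a GeoJSON file.
#' @return a list of `"contour"` objects.
#' @export
read_contours <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$type) || doc$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  lapply(seq_along(doc$features), function(i) {
    f <- doc$features[[i]]
    p <- f$properties
    g <- f$geometry
    label <- sprintf("feature %d (lesion '%s')", i,
                     if (is.null(p$lesion_id)) "?" else p$lesion_id)
    if (is.null(g$type) || !g$type %in% c("Polygon", "MultiPolygon"))
      stop("malformed geometry in ", label, ": expected Polygon or MultiPolygon")
    ring_from_coords <- function(rc) {
      m <- do.call(rbind, lapply(rc, function(xy) as.numeric(unlist(xy))))
      if (is.null(m) || ncol(m) != 2L)
        stop("malformed geometry in ", label, ": ring is not a 2-D coordinate list")
      m
    }
    rings <- if (g$type == "Polygon") {
      lapply(g$coordinates, ring_from_coords)
    } else {
      unlist(lapply(g$coordinates, function(poly) lapply(poly, ring_from_coords)),
             recursive = FALSE)
    }
    tryCatch(
      contour(rings, lesion_id = p$lesion_id, grader = p$grader,
              modality = p$modality, frame = p$frame),
      error = function(e) stop("invalid contour in ", label, ": ",
                               conditionMessage(e), call. = FALSE))
  })
}

#' Write contour annotations to GeoJSON
#'
#' Inverse of [read_contours()]; the written file round-trips losslessly
#' (coordinates at full double precision, closing vertex made explicit as
#' GeoJSON requires).
#'
#' @param contours a list of `"contour"` objects (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path) {
  if (inherits(contours, "contour")) contours <- list(contours)
  features <- lapply(contours, function(ct) {
    rings <- lapply(ct$rings, function(r) {
      r <- rbind(r, r[1L, ])            # explicit closure
      lapply(seq_len(nrow(r)), function(i) as.numeric(r[i, ]))
    })
    geometry <- if (length(rings) == 1L) {
      list(type = "Polygon", coordinates = rings)
    } else {
      list(type = "MultiPolygon", coordinates = lapply(rings, list))
    }
    list(type = "Feature",
         properties = list(lesion_id = ct$lesion_id, grader = ct$grader,
                           modality = ct$modality, frame = ct$frame),
         geometry = geometry)
  })
  doc <- list(type = "FeatureCollection", features = features)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read landmark tables
#'
#' CSV with columns `modality`, `landmark_name`, `x_px`, `y_px`, and
#' optionally `mm_per_px` (a scale hint; the fitted transform scale takes
#' precedence whenever at least two landmarks are available).
#'
#' @param path path to a CSV file.
#' @return a named list of `"landmark_set"` objects, one per modality.
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("modality", "landmark_name", "x_px", "y_px")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$modality), function(d) {
    m <- cbind(d$x_px, d$y_px)
    rownames(m) <- d$landmark_name
    hint <- if ("mm_per_px" %in% names(d)) d$mm_per_px[1L] else NA_real_
    landmark_set(d$modality[1L], m, mm_per_px = hint)
  })
  out
}

#' Write landmark tables
#'
#' @param landmark_sets a (named) list of `"landmark_set"` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmark_sets, path) {
  if (inherits(landmark_sets, "landmark_set")) landmark_sets <- list(landmark_sets)
  df <- do.call(rbind, lapply(landmark_sets, function(ls) {
    data.frame(modality = ls$modality,
               landmark_name = rownames(ls$landmarks),
               x_px = ls$landmarks[, 1L], y_px = ls$landmarks[, 2L],
               mm_per_px = ls$mm_per_px, row.names = NULL)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read fields of view
#'
#' CSV with columns `modality`, `x_min`, `y_min`, `x_max`, `y_max` (mm,
#' reference frame).
#'
#' @param path path to a CSV file.
#' @return a named list of `"field_of_view"` objects.
#' @export
read_fovs <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("modality", "x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(df)))
    stop("FOV CSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    field_of_view(df$modality[i],
                  c(df$x_min[i], df$y_min[i], df$x_max[i], df$y_max[i])))
  names(out) <- df$modality
  out
}

#' Write fields of view
#'
#' @param fovs a (named) list of `"field_of_view"` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fovs <- function(fovs, path) {
  if (inherits(fovs, "field_of_view")) fovs <- list(fovs)
  df <- do.call(rbind, lapply(fovs, function(f)
    data.frame(modality = f$modality, x_min = f$rect[1L], y_min = f$rect[2L],
               x_max = f$rect[3L], y_max = f$rect[4L], row.names = NULL)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

PIGMENTATION_LEVELS <- c("nonpigmented", "mixed", "pigmented")
DIAGNOSES <- c("nevus", "melanoma")

#' Read per-lesion metadata
#'
#' CSV of lesion covariates feeding the regression models: `lesion_id`,
#' `patient_id` (the clustering unit), `pigmentation` (`nonpigmented`,
#' `mixed`, `pigmented`), `diagnosis` (`nevus`, `melanoma`),
#' `largest_basal_diameter_mm`, `thickness_mm`, `distance_to_nerve_mm`,
#' `distance_to_fovea_mm`, plus optional logical columns (e.g. `lipofuscin`,
#' `subretinal_fluid`, `rpe_changes`).
#'
#' @param path path to a CSV file.
#' @return a validated data.frame.
#' @export
read_lesion_meta <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_lesion_meta(df)
}

#' Validate per-lesion metadata
#'
#' @param df a data.frame of lesion covariates (see [read_lesion_meta()]).
#' @return `df` with `pigmentation` and `diagnosis` as factors.
#' @export
validate_lesion_meta <- function(df) {
  need <- c("lesion_id", "patient_id", "pigmentation", "diagnosis",
            "largest_basal_diameter_mm", "thickness_mm")
  if (!all(need %in% names(df)))
    stop("lesion metadata must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(as.character(df$pigmentation)), PIGMENTATION_LEVELS)
  if (length(bad))
    stop("unknown pigmentation category: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(as.character(df$diagnosis)), DIAGNOSES)
  if (length(bad))
    stop("unknown diagnosis: ", paste(bad, collapse = ", "))
  lencols <- intersect(c("largest_basal_diameter_mm", "thickness_mm",
                         "distance_to_nerve_mm", "distance_to_fovea_mm"),
                       names(df))
  for (cl in lencols)
    if (any(df[[cl]] < 0, na.rm = TRUE)) stop("negative length in column ", cl)
  df$pigmentation <- factor(df$pigmentation, levels = PIGMENTATION_LEVELS)
  df$diagnosis <- factor(df$diagnosis, levels = DIAGNOSES)
  df
}

#' Write per-lesion metadata
#'
#' @param df a data.frame of lesion covariates.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_lesion_meta <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

RESULT_COLUMNS <- c("lesion_id", "comparison", "hd95_mm", "hausdorff_mm",
                    "dice", "exceeds_2mm")

#' Write agreement records
#'
#' One CSV row per lesion-by-comparison agreement record, in a stable column
#' order (`lesion_id`, `comparison`, `hd95_mm`, `hausdorff_mm`, `dice`,
#' `exceeds_2mm`) with distances at fixed nine-decimal precision so that
#' read-back reproduces the records to well below any reported tolerance.
#'
#' @param records a data.frame of agreement records (see
#'   [evaluate_agreement()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  records <- validate_records(records)
  out <- records[, RESULT_COLUMNS]
  for (cl in c("hd95_mm", "hausdorff_mm", "dice"))
    out[[cl]] <- sprintf("%.9f", out[[cl]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read agreement records
#'
#' @param path path to a CSV written by [write_results()].
#' @return a data.frame of agreement records.
#' @export
read_results <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_records(df)
}

COMPARISONS <- c("g1_CFP_vs_multi", "g1_SLO_vs_multi",
                 "g2_CFP_vs_multi", "g2_SLO_vs_multi",
                 "g1_vs_g2_CFP", "g1_vs_g2_SLO")

validate_records <- function(records) {
  records <- as.data.frame(records)
  miss <- setdiff(RESULT_COLUMNS, names(records))
  if (length(miss))
    stop("agreement records missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(as.character(records$comparison)), COMPARISONS)
  if (length(bad)) stop("unknown comparison label(s): ", paste(bad, collapse = ", "))
  if (nrow(records)) {
    with(records, {
      if (any(hd95_mm < 0 | hd95_mm > hausdorff_mm + 1e-9))
        stop("invariant violated: 0 <= hd95_mm <= hausdorff_mm")
      if (any(dice < -1e-12 | dice > 1 + 1e-12, na.rm = TRUE))
        stop("invariant violated: 0 <= dice <= 1")
    })
  }
  records$exceeds_2mm <- as.logical(records$exceeds_2mm)
  records
}

#' Export a rasterized contour mask (visualization only)
#'
#' Renders the filled contour into a binary PNG at a configurable scale.
#' This raster is a convenience for eyeballing annotations; all metrics in
#' the package operate on the vector polygons.
#'
#' @param contour a `"contour"`.
#' @param path output PNG path.
#' @param mm_per_px raster resolution.
#' @param margin_mm margin added around the contour bounding box.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(contour, path, mm_per_px = 0.02, margin_mm = 0.5) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for mask export")
  all_pts <- do.call(rbind, contour$rings)
  xr <- range(all_pts[, 1L]) + c(-margin_mm, margin_mm)
  yr <- range(all_pts[, 2L]) + c(-margin_mm, margin_mm)
  nx <- ceiling(diff(xr) / mm_per_px); ny <- ceiling(diff(yr) / mm_per_px)
  gx <- xr[1L] + (seq_len(nx) - 0.5) * mm_per_px
  gy <- yr[1L] + (seq_len(ny) - 0.5) * mm_per_px
  gr <- expand.grid(x = gx, y = gy)
  inside <- rep.int(FALSE, nrow(gr))
  for (r in contour$rings)  # even-odd over rings
    inside <- xor(inside, cpp_points_in_ring(gr$x, gr$y, r[, 1L], r[, 2L]))
  img <- matrix(as.numeric(inside), nrow = ny, ncol = nx, byrow = TRUE)
  png::writePNG(img, path)
  invisible(path)
}
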