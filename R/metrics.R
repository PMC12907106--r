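#' Construct a field of view
#'
#' Axis-aligned rectangle describing the fundus region a modality captures,
#' in the millimetre reference frame.
#'
#' @param modality one of `"CFP"`, `"SLO"`, `"MULTI"`.
#' @param rect numeric length-4 `c(x_min, y_min, x_max, y_max)`, mm.
#' @return an object of class `"field_of_view"`.
#' @export
field_of_view <- function(modality, rect) {
  modality <- match.arg(modality, MODALITIES)
  rect <- as.numeric(rect)
  if (length(rect) != 4L || !(rect[1L] < rect[3L]) || !(rect[2L] < rect[4L]))
    stop("rect must be c(x_min, y_min, x_max, y_max) with x_min < x_max and y_min < y_max")
  structure(list(modality = modality, rect = rect), class = "field_of_view")
}

#' Largest region common to a set of fields of view
#'
#' Intersection rectangle of all supplied fields of view — the standardized
#' region on which annotations are compared (typically the OCT-sized frame).
#'
#' @param fovs a list of `"field_of_view"` objects (at least one).
#' @return a `"field_of_view"` with modality `"MULTI"`.
#' @export
common_region <- function(fovs) {
  if (inherits(fovs, "field_of_view")) fovs <- list(fovs)
  if (length(fovs) < 1L) stop("need at least one field of view")
  rects <- vapply(fovs, function(f) f$rect, numeric(4))
  rect <- c(max(rects[1L, ]), max(rects[2L, ]), min(rects[3L, ]), min(rects[4L, ]))
  if (!(rect[1L] < rect[3L] && rect[2L] < rect[4L]))
    stop("no common region: the fields of view do not overlap")
  field_of_view("MULTI", rect)
}

rect_ring <- function(rect) {
  cbind(c(rect[1L], rect[3L], rect[3L], rect[1L]),
        c(rect[2L], rect[2L], rect[4L], rect[4L]))
}

ring_inside_rect <- function(ring, rect, tol = 0) {
  all(ring[, 1L] >= rect[1L] - tol & ring[, 1L] <= rect[3L] + tol &
      ring[, 2L] >= rect[2L] - tol & ring[, 2L] <= rect[4L] + tol)
}

#' Crop a contour to a field of view
#'
#' Clips the contour polygon to the rectangle (exact convex clip). Contours
#' entirely inside the rectangle are returned bitwise unchanged. Cropping can
#' split a border into multiple closed parts; these are kept as a multi-ring
#' contour. Boundary points lying on the crop rectangle are identified later,
#' at densification time, via the `crop_rect` argument of [densify()].
#'
#' @param contour a `"contour"`.
#' @param fov a `"field_of_view"` (or a length-4 rect) to crop to.
#' @return a list of class `"crop_result"` with elements `cropped` (the
#'   clipped `"contour"`), `common_rect` (the `"field_of_view"` used), and
#'   `was_clipped` (TRUE iff clipping changed the geometry).
#' @export
crop_contour <- function(contour, fov) {
  stopifnot(inherits(contour, "contour"))
  if (inherits(fov, "field_of_view")) rect <- fov$rect else rect <- as.numeric(fov)
  if (length(rect) != 4L) stop("invalid crop rectangle")
  inside <- all(vapply(contour$rings, ring_inside_rect, logical(1), rect = rect))
  if (inside) {
    return(structure(list(cropped = contour,
                          common_rect = field_of_view("MULTI", rect),
                          was_clipped = FALSE),
                     class = "crop_result"))
  }
  out <- polyclip::polyclip(rings_to_pc(contour$rings),
                            rings_to_pc(list(rect_ring(rect))),
                            op = "intersection")
  if (length(out) == 0L)
    stop("empty after crop: contour of lesion '", contour$lesion_id,
         "' lies outside the common field of view")
  cropped <- contour
  cropped$rings <- lapply(pc_to_rings(out), function(r) {
    r <- clean_ring(r)
    if (ring_area(r) < 0) r[rev(seq_len(nrow(r))), , drop = FALSE] else r
  })
  structure(list(cropped = cropped,
                 common_rect = field_of_view("MULTI", rect),
                 was_clipped = TRUE),
            class = "crop_result")
}

#' Densify a contour boundary into an arc-length point set
#'
#' Resamples each boundary edge so that consecutive points are at most
#' `spacing_mm` apart (original vertices are always retained), producing the
#' discrete stand-in for "every boundary point" used by the distance metrics.
#'
#' @param contour a `"contour"`.
#' @param spacing_mm target arc-length spacing (> 0), mm. The default 0.01 mm
#'   sits two orders of magnitude below the 2 mm clinical threshold.
#' @param crop_rect optional crop rectangle (`"field_of_view"` or length-4
#'   rect); points lying on its border (within `edge_tol`) are flagged
#'   `on_crop_edge`.
#' @param edge_tol tolerance for the crop-edge flag, mm.
#' @return an object of class `"boundary_points"`: a list with `points`
#'   (`n x 2` matrix), `ring` (ring index per point), `spacing_mm`, and
#'   `on_crop_edge` (logical per point).
#' @export
densify <- function(contour, spacing_mm = 0.01, crop_rect = NULL,
                    edge_tol = 1e-6) {
  stopifnot(inherits(contour, "contour"), spacing_mm > 0)
  pts <- vector("list", length(contour$rings))
  ring_id <- vector("list", length(contour$rings))
  for (k in seq_along(contour$rings)) {
    r <- contour$rings[[k]]
    nxt <- r[c(seq_len(nrow(r))[-1L], 1L), , drop = FALSE]
    seg <- nxt - r
    len <- sqrt(rowSums(seg^2))
    nsub <- pmax(1L, ceiling(len / spacing_mm))
    idx <- rep.int(seq_len(nrow(r)), nsub)
    tt <- (sequence(nsub) - 1L) / nsub[idx]
    pts[[k]] <- r[idx, , drop = FALSE] + tt * seg[idx, , drop = FALSE]
    ring_id[[k]] <- rep.int(k, length(idx))
  }
  points <- do.call(rbind, pts)
  on_edge <- rep.int(FALSE, nrow(points))
  if (!is.null(crop_rect)) {
    rect <- if (inherits(crop_rect, "field_of_view")) crop_rect$rect else as.numeric(crop_rect)
    x <- points[, 1L]; y <- points[, 2L]
    on_edge <- (abs(x - rect[1L]) <= edge_tol | abs(x - rect[3L]) <= edge_tol |
                abs(y - rect[2L]) <= edge_tol | abs(y - rect[4L]) <= edge_tol) &
      x >= rect[1L] - edge_tol & x <= rect[3L] + edge_tol &
      y >= rect[2L] - edge_tol & y <= rect[4L] + edge_tol
  }
  structure(list(points = points, ring = unlist(ring_id),
                 spacing_mm = spacing_mm, on_crop_edge = on_edge),
            class = "boundary_points")
}

#' Shortest distances from boundary points to a contour
#'
#' For each point of `a`, the exact Euclidean distance to the nearest point
#' of `b`'s boundary polylines (point-to-segment projection, never
#' point-to-vertex only, so the result does not depend on how finely `b` is
#' densified).
#'
#' @param a a `"boundary_points"` set.
#' @param b a `"contour"` in the same frame.
#' @return numeric vector of distances, one per point of `a`.
#' @export
directed_distances <- function(a, b) {
  stopifnot(inherits(a, "boundary_points"), inherits(b, "contour"))
  if (nrow(a$points) == 0L) stop("empty boundary point set")
  e <- lapply(b$rings, ring_edges)
  cpp_min_segment_distance(
    a$points[, 1L], a$points[, 2L],
    unlist(lapply(e, `[[`, "ax")), unlist(lapply(e, `[[`, "ay")),
    unlist(lapply(e, `[[`, "bx")), unlist(lapply(e, `[[`, "by")))
}

pooled_distance_sets <- function(a, b, spacing_mm, edge_policy, crop_rect) {
  edge_policy <- match.arg(edge_policy, c("include", "exclude"))
  bp_a <- densify(a, spacing_mm, crop_rect = crop_rect)
  bp_b <- densify(b, spacing_mm, crop_rect = crop_rect)
  keep_a <- rep.int(TRUE, nrow(bp_a$points))
  keep_b <- rep.int(TRUE, nrow(bp_b$points))
  if (edge_policy == "exclude") {
    keep_a <- !bp_a$on_crop_edge
    keep_b <- !bp_b$on_crop_edge
    if (!any(keep_a) || !any(keep_b))
      stop("undefined metric: no boundary points remain after excluding crop-edge points")
  }
  d_ab <- directed_distances(bp_a, b)[keep_a]
  d_ba <- directed_distances(bp_b, a)[keep_b]
  list(d_ab = d_ab, d_ba = d_ba)
}

#' Percentile Hausdorff distance between two contours
#'
#' The agreement metric of the pipeline: boundary points of each annotation
#' are densified at `spacing_mm`, shortest distances to the other annotation's
#' boundary are collected in both directions, and the configured percentile is
#' taken. With `method = "pooled"` (default) the percentile is taken over the
#' pooled two-directional distance set, so the metric is symmetric in its
#' arguments; `method = "max_directed"` takes the maximum of the two one-sided
#' percentiles. Percentiles use linear interpolation between order statistics.
#'
#' @param a,b `"contour"` objects in the same frame (crop both to the common
#'   field of view first; pass the same `crop_rect` used for cropping when an
#'   edge policy other than `"include"` is wanted).
#' @param percentile percentile in (0, 100]; 95 gives HD95, 100 the full
#'   Hausdorff distance.
#' @param method `"pooled"` or `"max_directed"`.
#' @param spacing_mm densification spacing, mm.
#' @param edge_policy `"include"` keeps boundary points introduced by
#'   cropping; `"exclude"` drops points flagged as lying on the crop
#'   rectangle (requires `crop_rect`).
#' @param crop_rect the crop rectangle used to flag crop-edge points.
#' @return distance in mm.
#' @examples
#' circ <- function(r) contour(cbind(r * cos(seq(0, 2 * pi, length.out = 721)[-721]),
#'                                   r * sin(seq(0, 2 * pi, length.out = 721)[-721])))
#' hd95(circ(2), circ(2.5), spacing_mm = 0.05)  # ~0.5 mm radial gap
#' @export
hd95 <- function(a, b, percentile = 95, method = c("pooled", "max_directed"),
                 spacing_mm = 0.01, edge_policy = "include", crop_rect = NULL) {
  stopifnot(inherits(a, "contour"), inherits(b, "contour"))
  if (!identical(a$frame, b$frame))
    stop("frame mismatch: contours are in frames '", a$frame, "' and '", b$frame, "'")
  if (!(percentile > 0 && percentile <= 100))
    stop("percentile must be in (0, 100]")
  method <- match.arg(method)
  d <- pooled_distance_sets(a, b, spacing_mm, edge_policy, crop_rect)
  if (method == "pooled") {
    quantile(c(d$d_ab, d$d_ba), percentile / 100, type = 7, names = FALSE)
  } else {
    max(quantile(d$d_ab, percentile / 100, type = 7, names = FALSE),
        quantile(d$d_ba, percentile / 100, type = 7, names = FALSE))
  }
}

#' Full Hausdorff distance between two contours
#'
#' The maximum over all pooled point-to-boundary distances; always at least
#' as large as [hd95()] at any percentile.
#'
#' @inheritParams hd95
#' @return distance in mm.
#' @export
hausdorff_distance <- function(a, b, spacing_mm = 0.01,
                               edge_policy = "include", crop_rect = NULL) {
  hd95(a, b, percentile = 100, method = "pooled", spacing_mm = spacing_mm,
       edge_policy = edge_policy, crop_rect = crop_rect)
}

#' Dice overlap coefficient between two contours
#'
#' `2 * area(a intersect b) / (area(a) + area(b))`, computed by exact polygon
#' intersection on the same (cropped) geometries the distance metrics use.
#'
#' @param a,b `"contour"` objects in the same frame with positive area.
#' @return overlap ratio in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(inherits(a, "contour"), inherits(b, "contour"))
  if (!identical(a$frame, b$frame))
    stop("frame mismatch: contours are in frames '", a$frame, "' and '", b$frame, "'")
  area_a <- contour_area(a); area_b <- contour_area(b)
  if (area_a <= 0 || area_b <= 0) stop("dice requires positive-area contours")
  if (identical(a$rings, b$rings)) return(1)   # exact, bypassing clipping
  inter <- polyclip::polyclip(rings_to_pc(a$rings), rings_to_pc(b$rings),
                              op = "intersection")
  area_i <- if (length(inter) == 0L) 0 else
    abs(sum(vapply(pc_to_rings(inter), ring_area, numeric(1))))
  min(1, max(0, 2 * area_i / (area_a + area_b)))
}

#' All agreement metrics for one contour pair
#'
#' Computes HD95, the full Hausdorff distance, and (optionally) Dice from a
#' single densification pass.
#'
#' @inheritParams hd95
#' @param threshold_mm clinical acceptability threshold for the exceedance
#'   flag (strict `>` comparison).
#' @param with_dice compute the Dice coefficient as well.
#' @return a list with `hd95_mm`, `hausdorff_mm`, `dice` (NA if not
#'   requested), and `exceeds` (`hd95_mm > threshold_mm`).
#' @export
pair_metrics <- function(a, b, percentile = 95,
                         method = c("pooled", "max_directed"),
                         spacing_mm = 0.01, edge_policy = "include",
                         crop_rect = NULL, threshold_mm = 2,
                         with_dice = TRUE) {
  stopifnot(inherits(a, "contour"), inherits(b, "contour"))
  if (!identical(a$frame, b$frame))
    stop("frame mismatch: contours are in frames '", a$frame, "' and '", b$frame, "'")
  method <- match.arg(method)
  d <- pooled_distance_sets(a, b, spacing_mm, edge_policy, crop_rect)
  pooled <- c(d$d_ab, d$d_ba)
  h95 <- if (method == "pooled") {
    quantile(pooled, percentile / 100, type = 7, names = FALSE)
  } else {
    max(quantile(d$d_ab, percentile / 100, type = 7, names = FALSE),
        quantile(d$d_ba, percentile / 100, type = 7, names = FALSE))
  }
  list(hd95_mm = h95, hausdorff_mm = max(pooled),
       dice = if (with_dice) dice_coefficient(a, b) else NA_real_,
       exceeds = h95 > threshold_mm)
}
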