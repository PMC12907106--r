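#' Construct a similarity transform
#'
#' Maps a source frame into a target frame by `p -> scale * R(rotation) %*% p
#' + translation`, with uniform positive scale and no reflection — the
#' minimal transform family consistent with spatial correspondence across
#' fundus imaging devices with different magnifications.
#'
#' @param scale positive uniform scale (net mm-per-px when mapping a pixel
#'   frame into the millimetre reference frame).
#' @param rotation rotation angle in radians.
#' @param translation numeric length-2 translation (target frame units).
#' @param rmse_mm root-mean-square landmark fit residual (0 for exact).
#' @param source_frame,target_frame frame tags (see [contour()]).
#' @return an object of class `"similarity_transform"`.
#' @export
similarity_transform <- function(scale, rotation, translation, rmse_mm = 0,
                                 source_frame = "pixel:CFP",
                                 target_frame = "reference_mm") {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0,
            length(translation) == 2L)
  structure(
    list(scale = scale, rotation = rotation,
         translation = as.numeric(translation), rmse_mm = rmse_mm,
         source_frame = source_frame, target_frame = target_frame),
    class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "<similarity_transform> %s -> %s\n  scale %.6g, rotation %.6g rad, translation (%.6g, %.6g), rmse %.3g mm\n",
    x$source_frame, x$target_frame, x$scale, x$rotation,
    x$translation[1L], x$translation[2L], x$rmse_mm))
  invisible(x)
}

rot_mat <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

#' Map points through a similarity transform
#'
#' @param t a `"similarity_transform"`.
#' @param pts `n x 2` matrix of source-frame points.
#' @return `n x 2` matrix of target-frame points.
#' @export
transform_points <- function(t, pts) {
  pts <- as.matrix(pts)
  co <- cos(t$rotation); si <- sin(t$rotation)
  out <- cbind(t$scale * (co * pts[, 1L] - si * pts[, 2L]) + t$translation[1L],
               t$scale * (si * pts[, 1L] + co * pts[, 2L]) + t$translation[2L],
               deparse.level = 0L)
  rownames(out) <- rownames(pts)
  out
}

#' Invert a similarity transform
#'
#' Composing a transform with its inverse yields the identity to within
#' floating-point round-off.
#'
#' @param t a `"similarity_transform"`.
#' @return the inverse `"similarity_transform"` (target -> source).
#' @export
invert_transform <- function(t) {
  Rinv <- rot_mat(-t$rotation)
  similarity_transform(
    scale = 1 / t$scale, rotation = -t$rotation,
    translation = as.numeric(-(Rinv %*% t$translation) / t$scale),
    rmse_mm = t$rmse_mm,
    source_frame = t$target_frame, target_frame = t$source_frame)
}

#' Construct a landmark set
#'
#' Named anatomical landmark coordinates (optic disc, fovea, vascular
#' bifurcations) in one modality's pixel frame, used to estimate the
#' transform into the common reference frame.
#'
#' @param modality one of `"CFP"`, `"SLO"`, `"MULTI"`.
#' @param landmarks a named `n x 2` matrix (rownames are landmark names drawn
#'   from the controlled vocabulary `optic_disc`, `fovea`, `bifurcation_<k>`).
#' @param mm_per_px optional scale hint; superseded by the fitted scale
#'   whenever two or more landmarks are available.
#' @return an object of class `"landmark_set"`.
#' @export
landmark_set <- function(modality, landmarks, mm_per_px = NA_real_) {
  modality <- match.arg(modality, MODALITIES)
  landmarks <- as.matrix(landmarks)
  if (is.null(rownames(landmarks)) || anyDuplicated(rownames(landmarks)))
    stop("landmarks must have unique rownames")
  ok <- grepl("^(optic_disc|fovea|bifurcation_[0-9]+)$", rownames(landmarks))
  if (!all(ok))
    stop("unknown landmark name(s): ",
         paste(rownames(landmarks)[!ok], collapse = ", "))
  if (nrow(landmarks) < 2L) stop("a landmark set needs at least 2 landmarks")
  structure(list(modality = modality, landmarks = landmarks,
                 mm_per_px = mm_per_px),
            class = "landmark_set")
}

#' Estimate the similarity transform between two landmark sets
#'
#' Closed-form least-squares similarity fit (uniform scale + rotation +
#' translation, reflection disallowed) over the landmarks shared by name
#' between the source and target sets, minimizing the sum of squared
#' target-frame residuals. With noiseless landmarks the recovery is exact
#' for any non-degenerate configuration of two or more points.
#'
#' @param source,target `"landmark_set"` objects; `target` coordinates are
#'   interpreted in the frame registered to (the millimetre reference frame
#'   in the pipeline, where the target set has `mm_per_px = 1`).
#' @param source_frame,target_frame frame tags recorded on the result;
#'   defaults follow the sets' modalities.
#' @return a `"similarity_transform"` with `rmse_mm` the root-mean-square
#'   landmark residual.
#' @export
estimate_transform <- function(source, target,
                               source_frame = paste0("pixel:", source$modality),
                               target_frame = "reference_mm") {
  stopifnot(inherits(source, "landmark_set"), inherits(target, "landmark_set"))
  shared <- intersect(rownames(source$landmarks), rownames(target$landmarks))
  if (length(shared) < 2L)
    stop("insufficient landmarks: need >= 2 shared between source and target, got ",
         length(shared))
  S <- source$landmarks[shared, , drop = FALSE]
  T_ <- target$landmarks[shared, , drop = FALSE]
  mu_s <- colMeans(S); mu_t <- colMeans(T_)
  Sc <- sweep(S, 2L, mu_s); Tc <- sweep(T_, 2L, mu_t)
  denom <- sum(Sc^2)
  if (denom < 1e-24)
    stop("degenerate landmark configuration: shared source landmarks coincide")
  # 2-D similarity least squares: a + ib = sum(conj(s) * t) in complex form
  a <- sum(Sc[, 1L] * Tc[, 1L] + Sc[, 2L] * Tc[, 2L])
  b <- sum(Sc[, 1L] * Tc[, 2L] - Sc[, 2L] * Tc[, 1L])
  scale <- sqrt(a^2 + b^2) / denom
  if (scale <= 0) stop("degenerate landmark configuration: zero fitted scale")
  theta <- atan2(b, a)
  trans <- mu_t - scale * as.numeric(rot_mat(theta) %*% mu_s)
  fit <- similarity_transform(scale, theta, trans,
                              source_frame = source_frame,
                              target_frame = target_frame)
  resid <- transform_points(fit, S) - T_
  fit$rmse_mm <- sqrt(mean(rowSums(resid^2)))
  fit
}

#' Map a contour through a similarity transform
#'
#' Every vertex is mapped and the frame tag is updated; the enclosed area
#' scales by the squared transform scale.
#'
#' @param contour a `"contour"` whose frame matches the transform's source
#'   frame.
#' @param t a `"similarity_transform"`.
#' @return the mapped `"contour"` in the transform's target frame.
#' @export
apply_transform <- function(contour, t) {
  stopifnot(inherits(contour, "contour"), inherits(t, "similarity_transform"))
  if (!identical(contour$frame, t$source_frame))
    stop("frame mismatch: contour is in '", contour$frame,
         "' but transform maps from '", t$source_frame, "'")
  out <- contour
  out$rings <- lapply(contour$rings, function(r) transform_points(t, r))
  out$frame <- t$target_frame
  out
}
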