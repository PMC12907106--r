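#' @useDynLib choroborder, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm runif rlnorm rbinom median sd pnorm pchisq setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

GRADERS    <- c("grader1", "grader2", "consensus")
MODALITIES <- c("CFP", "SLO", "MULTI")
FRAMES     <- c("reference_mm", paste0("pixel:", c("CFP", "SLO", "MULTI")))

## ---- low-level ring helpers (a ring is an n x 2 matrix, open, i.e. the
## closing edge last -> first is implicit) ----

ring_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- nrow(ring)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

ring_perimeter <- function(ring) {
  d <- ring[c(seq_len(nrow(ring))[-1L], 1L), , drop = FALSE] - ring
  sum(sqrt(rowSums(d^2)))
}

ring_edges <- function(ring) {
  nxt <- ring[c(seq_len(nrow(ring))[-1L], 1L), , drop = FALSE]
  list(ax = ring[, 1L], ay = ring[, 2L], bx = nxt[, 1L], by = nxt[, 2L])
}

# drop consecutive duplicate vertices and an explicit closing vertex
clean_ring <- function(ring, tol = 1e-12) {
  ring <- as.matrix(ring)
  if (nrow(ring) > 1L &&
      all(abs(ring[1L, ] - ring[nrow(ring), ]) <= tol)) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  if (nrow(ring) > 1L) {
    d <- rbind(diff(ring), ring[1L, ] - ring[nrow(ring), ])
    keep <- rowSums(abs(d)) > tol
    # keep[i] refers to edge i -> i+1; drop vertex i+1 when edge degenerate
    ring <- ring[c(TRUE, keep[-length(keep)]), , drop = FALSE]
  }
  ring
}

## ---- contour S3 class ----

#' Construct a contour annotation
#'
#' A contour is one closed planar border annotation of one lesion by one
#' grader on one modality (or the multimodal consensus). Vertices are stored
#' as one or more open rings (the closing edge is implicit); rings are
#' cleaned of consecutive duplicates, validated to be simple with positive
#' area, and normalized to counter-clockwise orientation.
#'
#' Multi-ring contours arise only from cropping to a field of view, which can
#' split a border into several closed parts.
#'
#' @param vertices an `n x 2` numeric matrix of vertices for a single ring,
#'   or a list of such matrices for a multi-part contour.
#' @param lesion_id character scalar identifying the lesion.
#' @param grader one of `"grader1"`, `"grader2"`, `"consensus"`.
#' @param modality one of `"CFP"`, `"SLO"`, `"MULTI"`.
#' @param frame coordinate frame tag: `"reference_mm"` for the common
#'   millimetre reference frame, or `"pixel:<modality>"` for a source pixel
#'   frame.
#' @param validate check invariants (at least 3 distinct vertices, simple,
#'   positive area). Internal callers constructing geometry known to be valid
#'   may skip this.
#' @return an object of class `"contour"`.
#' @examples
#' sq <- contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), "L1", "grader1", "CFP")
#' contour_area(sq)
#' @export
contour <- function(vertices, lesion_id = "lesion", grader = "grader1",
                    modality = "CFP", frame = "reference_mm",
                    validate = TRUE) {
  if (is.matrix(vertices) || is.data.frame(vertices)) {
    rings <- list(as.matrix(vertices))
  } else if (is.list(vertices)) {
    rings <- lapply(vertices, as.matrix)
  } else {
    stop("`vertices` must be a matrix or a list of matrices")
  }
  grader   <- match.arg(grader, GRADERS)
  modality <- match.arg(modality, MODALITIES)
  frame    <- match.arg(frame, FRAMES)
  rings <- lapply(rings, clean_ring)
  rings <- lapply(rings, function(r) {
    if (nrow(r) >= 3L && ring_area(r) < 0) r[rev(seq_len(nrow(r))), , drop = FALSE] else r
  })
  obj <- structure(
    list(lesion_id = as.character(lesion_id), grader = grader,
         modality = modality, frame = frame, rings = rings),
    class = "contour")
  if (validate) validate_contour(obj)
  obj
}

#' Validate a contour's invariants
#'
#' Checks that every ring has at least 3 distinct vertices, is simple
#' (non-self-intersecting), and that the total enclosed area is positive.
#'
#' @param x a `"contour"` object.
#' @return `x`, invisibly; errors describe the violated invariant.
#' @export
validate_contour <- function(x) {
  stopifnot(inherits(x, "contour"))
  if (length(x$rings) == 0L) stop("contour has no rings")
  for (r in x$rings) {
    if (nrow(r) < 3L)
      stop("contour ring of lesion '", x$lesion_id,
           "' has fewer than 3 distinct vertices")
    if (!cpp_ring_is_simple(r[, 1L], r[, 2L]))
      stop("contour ring of lesion '", x$lesion_id, "' is self-intersecting")
  }
  if (contour_area(x) <= 0)
    stop("contour of lesion '", x$lesion_id, "' has non-positive area")
  invisible(x)
}

#' Enclosed area of a contour
#'
#' Shoelace area summed over rings (rings of a multi-part contour are
#' disjoint, so areas add).
#'
#' @param x a `"contour"` object.
#' @return area, in squared frame units (mm^2 in the reference frame).
#' @export
contour_area <- function(x) sum(vapply(x$rings, ring_area, numeric(1)))

#' Boundary length of a contour
#'
#' @param x a `"contour"` object.
#' @return total perimeter over all rings, in frame units.
#' @export
contour_perimeter <- function(x) sum(vapply(x$rings, ring_perimeter, numeric(1)))

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> lesion %s | %s on %s | frame %s\n",
              x$lesion_id, x$grader, x$modality, x$frame))
  cat(sprintf("  %d ring(s), %d vertices, area %.4f, perimeter %.4f\n",
              length(x$rings), sum(vapply(x$rings, nrow, integer(1))),
              contour_area(x), contour_perimeter(x)))
  invisible(x)
}

# polyclip interchange: list of list(x=, y=) per ring
rings_to_pc <- function(rings) lapply(rings, function(r) list(x = r[, 1L], y = r[, 2L]))
pc_to_rings <- function(pc) lapply(pc, function(p) cbind(p$x, p$y))
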