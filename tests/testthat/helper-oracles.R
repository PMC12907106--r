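# Fixtures and independent oracles used across the suite.
# Oracles deliberately avoid the package's own computational paths:
# distances are enumerated with plain R arithmetic, areas by Monte-Carlo
# point counting with a standalone ray-casting test, the signed-rank null
# distribution by full sign enumeration, and the similarity fit by grid
# search.

circle_contour <- function(r, n = 360, center = c(0, 0), ...) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  contour(cbind(center[1] + r * cos(th), center[2] + r * sin(th)), ...)
}

# random star-shaped polygon (simple by construction; jittered angular grid
# keeps vertices well separated)
random_blob <- function(n = 24, r_base = 2, wobble = 0.5, center = c(0, 0)) {
  th <- (seq_len(n) - 1) * 2 * pi / n + runif(n, -0.3, 0.3) * 2 * pi / n
  r <- r_base * (1 + runif(n, -wobble, wobble))
  contour(cbind(center[1] + r * cos(th), center[2] + r * sin(th)))
}

# --- brute-force distance oracle (pure R, point-to-segment) ---
oracle_point_segment_dists <- function(pts, ring) {
  nxt <- ring[c(seq_len(nrow(ring))[-1], 1), , drop = FALSE]
  apply(pts, 1, function(p) {
    dx <- nxt[, 1] - ring[, 1]; dy <- nxt[, 2] - ring[, 2]
    len2 <- dx^2 + dy^2
    t <- ifelse(len2 > 0,
                pmin(1, pmax(0, ((p[1] - ring[, 1]) * dx +
                                   (p[2] - ring[, 2]) * dy) / len2)), 0)
    min(sqrt((p[1] - (ring[, 1] + t * dx))^2 +
               (p[2] - (ring[, 2] + t * dy))^2))
  })
}

oracle_densify_ring <- function(ring, spacing) {
  nxt <- ring[c(seq_len(nrow(ring))[-1], 1), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(ring))) {
    L <- sqrt(sum((nxt[i, ] - ring[i, ])^2))
    k <- max(1, ceiling(L / spacing))
    tt <- (seq_len(k) - 1) / k
    out[[i]] <- cbind(ring[i, 1] + tt * (nxt[i, 1] - ring[i, 1]),
                      ring[i, 2] + tt * (nxt[i, 2] - ring[i, 2]))
  }
  do.call(rbind, out)
}

# pooled percentile Hausdorff by direct enumeration (single-ring contours)
oracle_hd <- function(a, b, percentile, spacing) {
  ra <- a$rings[[1]]; rb <- b$rings[[1]]
  d_ab <- oracle_point_segment_dists(oracle_densify_ring(ra, spacing), rb)
  d_ba <- oracle_point_segment_dists(oracle_densify_ring(rb, spacing), ra)
  quantile(c(d_ab, d_ba), percentile / 100, type = 7, names = FALSE)
}

# --- Monte-Carlo area oracle (standalone ray casting) ---
oracle_in_ring <- function(px, py, ring) {
  n <- nrow(ring); inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]; xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# estimate of intersection area of two single-ring contours, with its MC sd
oracle_mc_intersection <- function(a, b, n_mc = 20000) {
  ra <- a$rings[[1]]; rb <- b$rings[[1]]
  lo <- pmin(apply(ra, 2, min), apply(rb, 2, min))
  hi <- pmax(apply(ra, 2, max), apply(rb, 2, max))
  px <- runif(n_mc, lo[1], hi[1]); py <- runif(n_mc, lo[2], hi[2])
  hit <- oracle_in_ring(px, py, ra) & oracle_in_ring(px, py, rb)
  box <- prod(hi - lo)
  p <- mean(hit)
  list(area = box * p, sd = box * sqrt(p * (1 - p) / n_mc))
}

# --- exact signed-rank two-sided p by full 2^n sign enumeration ---
oracle_signrank_p <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.numeric(signs %*% r)
  mu <- n * (n + 1) / 4
  mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-12)
}

# --- grid-search similarity-fit oracle (translation profiled out) ---
oracle_similarity_grid <- function(src, tgt, scale_grid, theta_grid) {
  best <- list(sse = Inf)
  mu_s <- colMeans(src); mu_t <- colMeans(tgt)
  Sc <- sweep(src, 2, mu_s); Tc <- sweep(tgt, 2, mu_t)
  for (s in scale_grid) for (th in theta_grid) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    resid <- Tc - s * Sc %*% t(R)
    sse <- sum(resid^2)
    if (sse < best$sse) best <- list(sse = sse, scale = s, theta = th)
  }
  best
}

make_landmarks <- function(xy, modality = "CFP", mm_per_px = NA_real_) {
  rownames(xy) <- c("optic_disc", "fovea",
                    paste0("bifurcation_", seq_len(nrow(xy) - 2)))[seq_len(nrow(xy))]
  landmark_set(modality, xy, mm_per_px = mm_per_px)
}

# small, fast pipeline configuration used across tests
fast_config <- function(...) {
  pipeline_config(densify_spacing_mm = 0.05, ...)
}
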