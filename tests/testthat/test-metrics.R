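test_that("common_region intersects fields of view and flags disjoint ones", {
  f1 <- field_of_view("MULTI", c(0, 0, 10, 10))
  expect_equal(common_region(list(f1))$rect, c(0, 0, 10, 10))  # identity
  f2 <- field_of_view("CFP", c(2, 1, 12, 9))
  expect_equal(common_region(list(f1, f2))$rect, c(2, 1, 10, 9))
  f3 <- field_of_view("SLO", c(20, 20, 30, 30))
  expect_error(common_region(list(f1, f3)), "no common region")
  expect_error(field_of_view("CFP", c(5, 0, 5, 10)), "x_min < x_max")
})

test_that("crop_contour clips analytically and leaves interior contours alone", {
  sq <- contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  inside <- crop_contour(sq, c(-1, -1, 2, 2))
  expect_false(inside$was_clipped)
  expect_identical(inside$cropped$rings[[1]], sq$rings[[1]])  # bitwise

  half <- crop_contour(sq, c(-1, -1, 0.5, 2))
  expect_true(half$was_clipped)
  expect_equal(contour_area(half$cropped), 0.5, tolerance = 1e-8)

  expect_error(crop_contour(sq, c(5, 5, 6, 6)), "empty after crop")
})

test_that("crop areas match the Monte-Carlo point-in-region oracle", {
  set.seed(61)
  n_bad <- 0
  for (i in 1:100) {
    blob <- random_blob(n = 20, r_base = 2, wobble = 0.6)
    rect <- c(runif(1, -2, 0), runif(1, -2, 0), runif(1, 0.5, 3), runif(1, 0.5, 3))
    res <- tryCatch(crop_contour(blob, rect), error = function(e) NULL)
    if (is.null(res)) next
    # MC estimate of area(blob intersect rect) over the rect box
    n_mc <- 8000
    px <- runif(n_mc, rect[1], rect[3]); py <- runif(n_mc, rect[2], rect[4])
    hit <- oracle_in_ring(px, py, blob$rings[[1]])
    box <- (rect[3] - rect[1]) * (rect[4] - rect[2])
    est <- box * mean(hit)
    sd_mc <- box * sqrt(mean(hit) * (1 - mean(hit)) / n_mc)
    z <- (contour_area(res$cropped) - est) / max(sd_mc, 1e-12)
    if (abs(z) > 3) n_bad <- n_bad + 1
  }
  # a few 3-sigma excursions among 100 binomial checks are expected noise
  expect_lte(n_bad, 3)
})

test_that("densify respects spacing, retains vertices, and converges", {
  circ <- circle_contour(1, n = 100)
  bp <- densify(circ, 0.01)
  expect_gte(nrow(bp$points), ceiling(2 * pi / 0.01))  # perimeter arithmetic
  # all points on the source boundary
  d <- directed_distances(bp, circ)
  expect_lt(max(oracle_point_segment_dists(bp$points, circ$rings[[1]])), 1e-9)

  # consecutive spacing bound: no gap exceeds 1.5 x target spacing
  gaps <- sqrt(rowSums((bp$points[c(2:nrow(bp$points), 1), ] - bp$points)^2))
  expect_lt(max(gaps), 1.5 * 0.01)

  # spacing larger than the perimeter: original vertices only
  tri <- contour(cbind(c(0, 1, 0), c(0, 0, 1)))
  expect_equal(nrow(densify(tri, 100)$points), 3)
  expect_equal(densify(tri, 100)$points, tri$rings[[1]])

  # halving the spacing barely moves HD95 on a random pair
  set.seed(71)
  a <- random_blob(); b <- random_blob()
  h1 <- hd95(a, b, spacing_mm = 0.02)
  h2 <- hd95(a, b, spacing_mm = 0.01)
  expect_lt(abs(h1 - h2), 1e-3)
})

test_that("directed distances equal brute-force point-to-segment enumeration", {
  # analytic: point to vertical segment
  seg <- contour(cbind(c(1, 1, 2), c(0, 1, 0.5)))
  bp <- structure(list(points = cbind(0, 0), ring = 1L, spacing_mm = 1,
                       on_crop_edge = FALSE), class = "boundary_points")
  expect_equal(directed_distances(bp, seg)[1], 1.0)

  set.seed(81)
  for (i in 1:10) {
    a <- random_blob(n = 15); b <- random_blob(n = 17, center = c(0.5, 0.3))
    bp <- densify(a, 0.25)
    expect_equal(directed_distances(bp, b),
                 oracle_point_segment_dists(bp$points, b$rings[[1]]),
                 tolerance = 1e-12)
  }

  # points on the target boundary give zeros
  circ <- circle_contour(2, n = 50)
  expect_lt(max(directed_distances(densify(circ, 0.05), circ)), 1e-12)
})

test_that("hd95 and hausdorff match analytic values and the brute-force oracle", {
  circ <- circle_contour(2, n = 1440)
  expect_equal(hd95(circ, circ, spacing_mm = 0.05), 0)
  expect_equal(hausdorff_distance(circ, circ, spacing_mm = 0.05), 0)

  big <- circle_contour(2.5, n = 1440)
  expect_equal(hd95(circ, big, spacing_mm = 0.02), 0.5, tolerance = 1e-3)
  expect_equal(hausdorff_distance(circ, big, spacing_mm = 0.02), 0.5,
               tolerance = 1e-3)

  shifted <- circle_contour(1, n = 1440, center = c(0.4, 0))
  unit <- circle_contour(1, n = 1440)
  expect_equal(hausdorff_distance(unit, shifted, spacing_mm = 0.02), 0.4,
               tolerance = 1e-3)

  set.seed(91)
  for (i in 1:25) {
    a <- random_blob(n = 8); b <- random_blob(n = 8, center = c(0.8, -0.4))
    expect_equal(hd95(a, b, spacing_mm = 0.1),
                 oracle_hd(a, b, 95, 0.1), tolerance = 1e-12)
    expect_equal(hausdorff_distance(a, b, spacing_mm = 0.1),
                 oracle_hd(a, b, 100, 0.1), tolerance = 1e-12)
    # definition consistency: hausdorff is hd95 at percentile 100
    expect_equal(hausdorff_distance(a, b, spacing_mm = 0.1),
                 hd95(a, b, percentile = 100, spacing_mm = 0.1))
  }
})

test_that("hd95 metric properties: symmetry, ordering, percentile monotonicity", {
  set.seed(101)
  for (i in 1:10) {
    a <- random_blob(); b <- random_blob(center = c(1, 0))
    h_ab <- hd95(a, b, spacing_mm = 0.05)
    expect_equal(h_ab, hd95(b, a, spacing_mm = 0.05))          # pooled symmetry
    expect_gte(hausdorff_distance(a, b, spacing_mm = 0.05), h_ab)
    ps <- c(50, 75, 90, 95, 100)
    hs <- vapply(ps, function(p) hd95(a, b, percentile = p, spacing_mm = 0.05),
                 numeric(1))
    expect_true(all(diff(hs) >= -1e-12))                       # monotone in p
    expect_gte(min(hs), 0)
    # max_directed never below pooled at the same percentile
    expect_gte(hd95(a, b, method = "max_directed", spacing_mm = 0.05) + 1e-12,
               h_ab)
  }
  expect_error(hd95(random_blob(), random_blob(), percentile = 120),
               "percentile")
})

test_that("metrics are rigid-invariant and scale-covariant", {
  set.seed(111)
  a <- random_blob(); b <- random_blob(center = c(0.7, 0.2))
  h0 <- hd95(a, b, spacing_mm = 0.02)
  f0 <- hausdorff_distance(a, b, spacing_mm = 0.02)
  d0 <- dice_coefficient(a, b)
  for (i in 1:5) {
    t_rigid <- similarity_transform(1, runif(1, -pi, pi), runif(2, -10, 10),
                                    source_frame = "reference_mm",
                                    target_frame = "reference_mm")
    a2 <- apply_transform(a, t_rigid); b2 <- apply_transform(b, t_rigid)
    expect_equal(hd95(a2, b2, spacing_mm = 0.02), h0, tolerance = 1e-6)
    expect_equal(hausdorff_distance(a2, b2, spacing_mm = 0.02), f0,
                 tolerance = 1e-6)
    expect_equal(dice_coefficient(a2, b2), d0, tolerance = 1e-6)
  }
  s <- 2.5
  t_scale <- similarity_transform(s, 0, c(0, 0),
                                  source_frame = "reference_mm",
                                  target_frame = "reference_mm")
  a3 <- apply_transform(a, t_scale); b3 <- apply_transform(b, t_scale)
  # spacing scaled along so the densification is geometrically identical
  expect_equal(hd95(a3, b3, spacing_mm = 0.02 * s), s * h0, tolerance = 1e-9)
  expect_equal(hausdorff_distance(a3, b3, spacing_mm = 0.02 * s), s * f0,
               tolerance = 1e-9)
  expect_equal(dice_coefficient(a3, b3), d0, tolerance = 1e-6)
})

test_that("dice matches analytic overlaps and bounds", {
  circ1 <- circle_contour(1, n = 1440)
  circ2 <- circle_contour(2, n = 1440)
  expect_equal(dice_coefficient(circ1, circ1), 1.0, tolerance = 1e-9)
  expect_equal(dice_coefficient(circ1, circ2), 0.4, tolerance = 1e-3)
  far <- circle_contour(1, n = 100, center = c(10, 10))
  expect_equal(dice_coefficient(circ1, far), 0.0)
  sq1 <- contour(cbind(c(0, 2, 2, 0), c(0, 0, 1, 1)))
  sq2 <- contour(cbind(c(1, 3, 3, 1), c(0, 0, 1, 1)))
  expect_equal(dice_coefficient(sq1, sq2), 2 * 1 / (2 + 2), tolerance = 1e-8)
  expect_error(dice_coefficient(sq1, contour(sq2$rings[[1]], frame = "pixel:CFP")),
               "frame mismatch")
})

test_that("crop-edge policy: excluding coincident crop edges cannot deflate HD95", {
  set.seed(121)
  for (i in 1:8) {
    a <- random_blob(n = 20, r_base = 2)
    b <- random_blob(n = 20, r_base = 2)
    rect <- c(-3, -3, runif(1, 0, 1.5), 3)   # cut through both blobs
    ca <- tryCatch(crop_contour(a, rect)$cropped, error = function(e) NULL)
    cb <- tryCatch(crop_contour(b, rect)$cropped, error = function(e) NULL)
    if (is.null(ca) || is.null(cb)) next
    h_inc <- hd95(ca, cb, spacing_mm = 0.05, edge_policy = "include",
                  crop_rect = rect)
    h_exc <- tryCatch(
      hd95(ca, cb, spacing_mm = 0.05, edge_policy = "exclude",
           crop_rect = rect),
      error = function(e) NA_real_)
    if (!is.na(h_exc)) expect_gte(h_exc + 1e-9, h_inc)
  }
})

test_that("pair_metrics is consistent with the individual metrics", {
  set.seed(131)
  a <- random_blob(); b <- random_blob(center = c(0.5, 0))
  m <- pair_metrics(a, b, spacing_mm = 0.05, threshold_mm = 2)
  expect_equal(m$hd95_mm, hd95(a, b, spacing_mm = 0.05))
  expect_equal(m$hausdorff_mm, hausdorff_distance(a, b, spacing_mm = 0.05))
  expect_equal(m$dice, dice_coefficient(a, b))
  expect_identical(m$exceeds, m$hd95_mm > 2)
  expect_gte(m$hausdorff_mm, m$hd95_mm)
})
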