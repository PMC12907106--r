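test_that("truth contours honor diameter and degenerate to circles", {
  set.seed(261)
  circ <- sample_truth_contour(5.65, shape_irregularity = 0)
  rel <- sweep(circ$rings[[1]], 2, colMeans(circ$rings[[1]]))
  expect_lt(max(abs(sqrt(rowSums(rel^2)) - 5.65 / 2)), 1e-9)

  # largest en-face extent equals the stated diameter, including for
  # irregular shapes (the generator rescales to the drawn diameter)
  for (i in 1:10) {
    tr <- sample_truth_contour(5.65, shape_irregularity = 0.2, n_vertices = 96)
    expect_equal(max(stats::dist(tr$rings[[1]])), 5.65, tolerance = 1e-6)
    expect_silent(validate_contour(tr))
  }

  # sampled cohort diameters reproduce the configured median
  set.seed(271)
  d <- rlnorm(1000, log(5.65), 0.643)
  med_se <- 1.2533 * sd(d) / sqrt(length(d))   # asymptotic se of the median
  expect_lt(abs(median(d) - 5.65), 3 * med_se)
})

test_that("annotation noise behaves as configured", {
  set.seed(281)
  tr <- sample_truth_contour(6, 0.1, n_vertices = 96)
  # zero noise, no gross errors: annotation identical to truth
  ann0 <- perturb_annotation(tr, 0, gross_error = list(prob = 0,
                                                       arc_fraction = 0.1,
                                                       magnitude_mm = 3))
  expect_equal(ann0$rings[[1]], tr$rings[[1]], tolerance = 1e-12)
  expect_equal(hd95(ann0, tr, spacing_mm = 0.1), 0)

  # a guaranteed 3 mm gross bump yields HD95 vs truth in [2, 3] mm
  set.seed(291)
  h <- replicate(200, {
    tr <- sample_truth_contour(5.65, 0.1, n_vertices = 64)
    a <- perturb_annotation(tr, 0, gross_error = list(prob = 1,
                                                      arc_fraction = 0.12,
                                                      magnitude_mm = 3))
    hd95(a, tr, spacing_mm = 0.15)
  })
  expect_gte(min(h), 2.0)
  expect_lte(max(h), 3.0)

  # pigmentation-dependent noise induces the expected stochastic ordering
  set.seed(301)
  sd_pig <- 0.20; sd_non <- 0.42
  m <- vapply(list(sd_pig, sd_non), function(s) {
    mean(replicate(120, {
      tr <- sample_truth_contour(5.65, 0.1, n_vertices = 64)
      hd95(perturb_annotation(tr, s, NULL), tr, spacing_mm = 0.15)
    }))
  }, numeric(1))
  expect_gt(m[2], m[1])
})

test_that("cohort composition matches the study profile by construction", {
  coh <- generate_cohort(cohort_config(seed = 311))
  expect_equal(nrow(coh$meta), 64)
  expect_equal(length(unique(coh$meta$patient_id)), 63)
  expect_equal(as.vector(table(coh$meta$pigmentation)[c("nonpigmented", "mixed", "pigmented")]),
               c(11, 12, 41))
  expect_equal(sum(coh$meta$diagnosis == "nevus"), 39)
  expect_equal(sum(table(coh$meta$patient_id) == 2), 1)  # one two-lesion patient

  # infeasible configurations are rejected
  expect_error(cohort_config(n_lesions = 10, n_patients = 11), "infeasible")
  expect_error(cohort_config(pigmentation_props = c(nonpigmented = 0.5,
                                                    mixed = 0.5,
                                                    pigmented = 0.1)),
               "sum to 1")
})

test_that("one seed yields one cohort, byte for byte", {
  c1 <- generate_cohort(cohort_config(seed = 321, n_lesions = 6L,
                                      n_patients = 6L))
  c2 <- generate_cohort(cohort_config(seed = 321, n_lesions = 6L,
                                      n_patients = 6L))
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  c3 <- generate_cohort(cohort_config(seed = 322, n_lesions = 6L,
                                      n_patients = 6L))
  expect_false(identical(c1$meta, c3$meta) &&
                 identical(c1$lesions[[1]]$truth, c3$lesions[[1]]$truth))
})

test_that("generated landmarks round-trip to the sampled true transforms", {
  coh <- generate_cohort(cohort_config(seed = 331, n_lesions = 8L,
                                       n_patients = 8L))
  for (l in coh$lesions) {
    for (mod in c("CFP", "SLO")) {
      est <- estimate_transform(l$landmarks[[mod]], l$landmarks[["MULTI"]])
      tru <- l$true_transforms[[mod]]
      expect_equal(est$scale, tru$scale, tolerance = 1e-9)
      expect_equal(est$rotation, tru$rotation, tolerance = 1e-9)
      expect_equal(est$translation, tru$translation, tolerance = 1e-9)
      expect_lt(est$rmse_mm, 1e-9)
    }
  }
})

test_that("exceedance fraction rises monotonically with the gross-error rate", {
  probs <- c(0, 0.15, 0.5, 1)
  frac <- vapply(probs, function(p) {
    set.seed(341)   # common random numbers isolate the effect of p
    mean(replicate(80, {
      tr <- sample_truth_contour(5.65, 0.1, n_vertices = 48)
      a <- perturb_annotation(tr, 0.1,
                              gross_error = list(prob = p, arc_fraction = 0.12,
                                                 magnitude_mm = 3))
      hd95(a, tr, spacing_mm = 0.15) > 2
    }))
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_equal(frac[1], 0)
  expect_gt(frac[4], 0.9)
})

test_that("offset mode produces exactly controlled outcomes", {
  cc <- cohort_config(seed = 351, effect_mode = "offset", n_vertices = 64L,
                      n_lesions = 10L, n_patients = 10L)
  coh <- register_cohort(generate_cohort(cc))
  rec <- evaluate_agreement(coh, fast_config(),
                            comparisons = "g1_CFP_vs_multi", with_dice = FALSE)
  # consensus equals truth, so HD95 equals the drawn radial offset; all
  # offsets are near base + effect and never at the floor for these settings
  m <- merge(rec, coh$meta, by = "lesion_id")
  lo <- cc$offset_base_mm + cc$offset_effects_mm[as.character(m$pigmentation)]
  expect_lt(max(abs(m$hd95_mm - lo)), 5 * cc$offset_sd_mm)
  expect_gt(min(m$hd95_mm), 0.02)
})

test_that("cohort bundles are written complete and re-readable", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(cohort_config(seed = 361, n_lesions = 4L,
                                       n_patients = 4L))
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "annotations_pixel.geojson", "consensus_reference.geojson",
    "truth_reference.geojson", "landmarks.csv", "fovs.csv",
    "lesion_meta.csv", "manifest.json")))))
  ann <- read_contours(file.path(dir, "annotations_pixel.geojson"))
  expect_length(ann, 4 * 4)   # 2 graders x 2 modalities per lesion
  expect_true(all(startsWith(vapply(ann, `[[`, "", "frame"), "pixel:")))
  meta <- read_lesion_meta(file.path(dir, "lesion_meta.csv"))
  expect_equal(nrow(meta), 4)
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 361)
})
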