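test_that("signed-rank p-values match full sign enumeration on small samples", {
  # all-positive differences 1..5: W = 15, two-sided exact p = 2/32
  w <- wilcoxon_signed_rank(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_equal(w$statistic, 15)
  expect_identical(w$method, "exact")
  expect_equal(w$p_value, 0.0625)
  expect_equal(w$p_value, oracle_signrank_p(c(1, 2, 3, 4, 5)))

  set.seed(191)
  for (i in 1:15) {
    n <- sample(4:10, 1)
    d <- round(runif(n, 0.05, 5), 3) * sample(c(-1, 1), n, TRUE)
    while (anyDuplicated(abs(d))) d <- d + runif(n, 0, 1e-4)
    w <- wilcoxon_signed_rank(d, rep(0, n))
    expect_identical(w$method, "exact")
    expect_equal(w$p_value, oracle_signrank_p(d), tolerance = 1e-12)
  }
})

test_that("signed-rank handles zeros, ties, and degenerate input per policy", {
  expect_warning(res <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)),
                 "degenerate")
  expect_equal(res$p_value, 1)
  expect_equal(res$n_effective, 0)

  # zero differences are dropped before ranking
  w <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 9), c(1, 1, 1, 1, 1, 9))
  expect_equal(w$n_effective, 4)

  # ties in |d| force the normal approximation even for tiny n
  wt <- wilcoxon_signed_rank(c(2, 2, 3, 5), c(1, 1, 1, 1))
  expect_identical(wt$method, "normal_approx")

  # beyond the exact cutoff the approximation kicks in
  set.seed(201)
  big <- wilcoxon_signed_rank(rnorm(30, 0.5), rnorm(30))
  expect_identical(big$method, "normal_approx")
  expect_true(big$p_value >= 0 && big$p_value <= 1)
})

test_that("signed-rank is antisymmetric in its arguments", {
  set.seed(211)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    a <- suppressWarnings(wilcoxon_signed_rank(x, y))
    b <- suppressWarnings(wilcoxon_signed_rank(y, x))
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    m <- a$n_effective
    expect_equal(b$statistic, m * (m + 1) / 2 - a$statistic)
  }
})

test_that("GEE with singleton clusters reproduces OLS with HC0 sandwich errors", {
  set.seed(221)
  n <- 80
  x <- factor(sample(c("nonpigmented", "mixed", "pigmented"), n, TRUE))
  y <- 0.5 + 0.6 * (x == "nonpigmented") + 0.4 * (x == "mixed") + rnorm(n, 0, 0.3)
  cl <- sprintf("P%03d", seq_len(n))          # every cluster size 1
  fit <- fit_gaussian_gee(y, x, cl, reference = "pigmented")

  # independent oracle: lm + sandwich HC0
  xr <- stats::relevel(x, "pigmented")
  ols <- lm(y ~ xr)
  vc <- sandwich::vcovHC(ols, type = "HC0")
  nm <- paste0("xr", names(fit$coefficients))
  expect_equal(unname(fit$coefficients), unname(coef(ols)[nm]),
               tolerance = 1e-8)
  expect_equal(unname(fit$robust_se), unname(sqrt(diag(vc))[nm]),
               tolerance = 1e-8)
  expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-8)
  expect_equal(fit$n_clusters, n)

  # numeric predictor route matches lm too
  z <- rnorm(n)
  y2 <- 1 + 0.3 * z + rnorm(n, 0, 0.2)
  fit2 <- fit_gaussian_gee(y2, z, cl)
  ols2 <- lm(y2 ~ z)
  expect_equal(unname(fit2$coefficients), unname(coef(ols2)[2]),
               tolerance = 1e-8)
  expect_equal(unname(fit2$robust_se),
               sqrt(diag(sandwich::vcovHC(ols2, type = "HC0")))[[2]],
               tolerance = 1e-8)
})

test_that("balanced two-group GEE recovers the difference in group means", {
  y <- c(1, 2, 3, 7, 8, 9)
  g <- factor(rep(c("a", "b"), each = 3))
  fit <- fit_gaussian_gee(y, g, cluster = seq_along(y), reference = "a")
  expect_equal(unname(fit$coefficients["b"]), mean(y[4:6]) - mean(y[1:3]),
               tolerance = 1e-10)
})

test_that("sandwich errors are invariant to cluster relabeling", {
  set.seed(231)
  n <- 64
  cl <- c(sprintf("P%02d", 1:63), "P07")     # one two-lesion patient
  x <- factor(sample(c("nonpigmented", "mixed", "pigmented"), n, TRUE))
  y <- 0.4 + 0.3 * (x == "mixed") + rnorm(n, 0, 0.2)
  f1 <- fit_gaussian_gee(y, x, cl, reference = "pigmented")
  relabel <- setNames(sample(sprintf("Q%02d", 1:63)), unique(cl))
  f2 <- fit_gaussian_gee(y, x, relabel[cl], reference = "pigmented")
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$robust_se, f2$robust_se, tolerance = 1e-10)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-10)
})

test_that("exchangeable GEE exploits within-cluster correlation coherently", {
  # strongly correlated clusters: exchangeable and independence give the
  # same point estimates here (balanced design) but a positive alpha
  set.seed(241)
  n_cl <- 40
  u <- rnorm(n_cl, 0, 1)
  y <- as.vector(rbind(u + rnorm(n_cl, 0, 0.1), u + rnorm(n_cl, 0, 0.1)))
  x <- rep(rnorm(n_cl), each = 2)
  cl <- rep(seq_len(n_cl), each = 2)
  fex <- fit_gaussian_gee(y, x, cl, working_correlation = "exchangeable")
  find <- fit_gaussian_gee(y, x, cl, working_correlation = "independence")
  expect_gt(fex$alpha, 0.8)
  expect_equal(find$alpha, 0)
  expect_equal(unname(fex$coefficients), unname(find$coefficients),
               tolerance = 0.05)
})

test_that("GEE rejects unusable designs", {
  expect_error(fit_gaussian_gee(1:4, factor(c("a", "a", "b", "b")),
                                cluster = rep("P1", 4)), "2 clusters")
  x <- factor(c("a", "a", "a", "a"))
  expect_error(fit_gaussian_gee(1:4, x, cluster = 1:4), "singular|contrasts")
  expect_error(fit_gaussian_gee(1:4, factor(c("a", "b", "a", "b")), 1:4,
                                reference = "zz"), "reference level")
})

test_that("joint Wald test: 1-df identity, null at zero, and chi-squared tail", {
  set.seed(251)
  n <- 60
  x <- factor(sample(c("a", "b"), n, TRUE))
  y <- rnorm(n) + 0.8 * (x == "b")
  fit <- fit_gaussian_gee(y, x, seq_len(n), reference = "a")
  jt <- joint_wald_test(fit)
  expect_equal(jt$df, 1)
  expect_equal(jt$chi2, unname(fit$wald_z["b"]^2), tolerance = 1e-10)
  expect_equal(jt$p_value, unname(fit$p_values["b"]), tolerance = 1e-10)

  # hand-built fit with beta = 0: chi2 = 0, p = 1
  f0 <- structure(list(coefficients = c(u = 0, v = 0),
                       vcov_robust = diag(2)), class = "gee_fit")
  j0 <- joint_wald_test(f0)
  expect_equal(j0$chi2, 0)
  expect_equal(j0$p_value, 1)
  expect_equal(j0$df, 2)

  f_sing <- structure(list(coefficients = c(u = 1, v = 1),
                           vcov_robust = matrix(1, 2, 2)), class = "gee_fit")
  expect_error(joint_wald_test(f_sing), "singular")
})
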