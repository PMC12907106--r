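#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences `x - y`, following the
#' convention used throughout the pipeline for grader-vs-grader and
#' modality-vs-modality HD95 comparisons: zero differences are dropped, ranks
#' of `|d|` use midranks for ties, the statistic `W` is the sum of ranks of
#' positive differences, the p-value is exact (full sign-assignment
#' enumeration) when at most `exact_cutoff` nonzero differences remain and
#' `|d|` has no ties, and otherwise uses the normal approximation with tie
#' and continuity corrections. All-zero differences are a degenerate test:
#' a warning is issued and `p = 1` reported.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_cutoff largest `n_effective` for which the exact distribution
#'   is enumerated (default 12).
#' @param zero_tol absolute differences at or below this value count as zero
#'   differences. The default, 1e-9 (a millionth of a micrometre on the
#'   millimetre scale of the pipeline), discards floating-point dust without
#'   touching any measurable signal.
#' @return an object of class `"wilcoxon_result"`: a list with `n_effective`,
#'   `statistic` (W), `p_value`, and `method` (`"exact"` or
#'   `"normal_approx"`).
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
#' @export
wilcoxon_signed_rank <- function(x, y, exact_cutoff = 12, zero_tol = 1e-9) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  d <- x - y
  d <- d[!is.na(d)]
  d_nz <- d[abs(d) > zero_tol]
  n_eff <- length(d_nz)
  if (n_eff == 0L) {
    warning("degenerate signed-rank test: all paired differences are zero; p reported as 1")
    return(structure(list(n_effective = 0L, statistic = 0, p_value = 1,
                          method = "normal_approx"),
                     class = "wilcoxon_result"))
  }
  use_exact <- n_eff <= exact_cutoff && !anyDuplicated(abs(d_nz))
  ht <- suppressWarnings(
    stats::wilcox.test(d_nz, mu = 0, paired = FALSE, exact = use_exact,
                       correct = TRUE, alternative = "two.sided"))
  structure(list(n_effective = n_eff,
                 statistic = unname(ht$statistic),
                 p_value = min(1, ht$p.value),
                 method = if (use_exact) "exact" else "normal_approx"),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %g, n_eff = %d, p = %.4g (%s)\n",
              x$statistic, x$n_effective, x$p_value, x$method))
  invisible(x)
}

#' The pipeline's paired HD95 comparisons
#'
#' Runs the study's paired signed-rank comparisons on a set of agreement
#' records: between-grader agreement across modalities (interrater CFP vs
#' SLO), each grader's CFP vs SLO agreement with the multimodal reference,
#' and grader 1 vs grader 2 within each modality.
#'
#' @param records agreement records (see [evaluate_agreement()]).
#' @return a data.frame with one row per comparison (`label`, `n_effective`,
#'   `W`, `p_value`, `method`).
#' @export
wilcoxon_comparisons <- function(records) {
  wide <- hd95_wide(records)
  pairs <- list(
    interrater_CFP_vs_SLO = c("g1_vs_g2_CFP", "g1_vs_g2_SLO"),
    g1_CFP_vs_SLO         = c("g1_CFP_vs_multi", "g1_SLO_vs_multi"),
    g2_CFP_vs_SLO         = c("g2_CFP_vs_multi", "g2_SLO_vs_multi"),
    g1_vs_g2_on_CFP       = c("g1_CFP_vs_multi", "g2_CFP_vs_multi"),
    g1_vs_g2_on_SLO       = c("g1_SLO_vs_multi", "g2_SLO_vs_multi"))
  out <- lapply(names(pairs), function(lbl) {
    cols <- pairs[[lbl]]
    if (!all(cols %in% names(wide))) return(NULL)
    w <- wilcoxon_signed_rank(wide[[cols[1L]]], wide[[cols[2L]]])
    data.frame(label = lbl, n_effective = w$n_effective, W = w$statistic,
               p_value = w$p_value, method = w$method)
  })
  do.call(rbind, out)
}

hd95_wide <- function(records) {
  records <- as.data.frame(records)
  wide <- stats::reshape(
    records[, c("lesion_id", "comparison", "hd95_mm")],
    idvar = "lesion_id", timevar = "comparison", direction = "wide")
  names(wide) <- sub("^hd95_mm\\.", "", names(wide))
  wide
}

#' Univariable Gaussian GEE with cluster-robust errors
#'
#' Identity-link Gaussian generalized estimating equations relating an
#' outcome (HD95, in the pipeline) to a single predictor, with observations
#' clustered (by patient) and variance estimated by the cluster-level
#' sandwich. Categorical predictors are expanded to indicators against a
#' declared reference level, so coefficients are adjusted mean differences
#' (delta-mean) versus the reference. Estimation iterates weighted least
#' squares with the working correlation's moment estimator until
#' `max |delta beta| < tol`.
#'
#' With every cluster of size 1 the fit reduces exactly to ordinary least
#' squares with heteroskedasticity-robust (HC0) standard errors.
#'
#' @param outcome numeric outcome vector.
#' @param predictor numeric vector, or factor/character for categorical
#'   predictors.
#' @param cluster cluster identifiers (patient ids), same length.
#' @param reference reference level for categorical predictors (default: the
#'   factor's first level; the pipeline uses `"pigmented"` for pigmentation).
#' @param working_correlation `"exchangeable"` (default; patients contribute
#'   one or two lesions) or `"independence"`.
#' @param tol convergence tolerance on `max |delta beta|`.
#' @param maxit iteration cap; non-convergence is an error reporting the
#'   iteration trace.
#' @return an object of class `"gee_fit"`: coefficients (non-reference),
#'   `robust_se`, `wald_z`, `p_values`, `vcov_robust`, `n_obs`, `n_clusters`,
#'   `alpha` (estimated exchangeable correlation), `dispersion`, plus the
#'   intercept estimate.
#' @export
fit_gaussian_gee <- function(outcome, predictor, cluster,
                             reference = NULL,
                             working_correlation = c("exchangeable",
                                                     "independence"),
                             tol = 1e-8, maxit = 100L) {
  working_correlation <- match.arg(working_correlation)
  keep <- !(is.na(outcome) | is.na(predictor) | is.na(cluster))
  y <- as.numeric(outcome[keep])
  cl <- as.character(cluster[keep])
  pr <- predictor[keep]
  if (length(unique(cl)) < 2L) stop("need at least 2 clusters")

  if (is.character(pr)) pr <- factor(pr)
  if (is.factor(pr)) {
    pr <- droplevels(pr)
    if (!is.null(reference)) {
      if (!reference %in% levels(pr))
        stop("reference level '", reference, "' not present in predictor")
      pr <- stats::relevel(pr, ref = reference)
    }
    X <- stats::model.matrix(~pr)
    colnames(X) <- c("(Intercept)", levels(pr)[-1L])
    ref_level <- levels(pr)[1L]
  } else {
    X <- cbind("(Intercept)" = 1, predictor = as.numeric(pr))
    ref_level <- NA_character_
  }
  if (qr(X)$rank < ncol(X))
    stop("singular design: predictor has linearly dependent levels")

  idx <- split(seq_along(y), cl)
  n <- length(y); p <- ncol(X)

  beta <- qr.solve(X, y)               # OLS start
  alpha <- 0
  trace <- numeric(0)
  for (it in seq_len(maxit)) {
    e <- y - as.numeric(X %*% beta)
    phi <- sum(e^2) / (n - p)
    d_alpha <- 0
    if (working_correlation == "exchangeable") {
      num <- 0; npairs <- 0
      for (ix in idx) {
        ni <- length(ix)
        if (ni > 1L) {
          ei <- e[ix]
          num <- num + (sum(ei)^2 - sum(ei^2)) / 2
          npairs <- npairs + ni * (ni - 1) / 2
        }
      }
      # with fewer residual pairs than parameters the moment estimator of
      # alpha is pure noise (and a single clamped pair can dominate the
      # weighted fit); fall back to the independence weights in that case
      if (npairs - p <= 0) {
        alpha_new <- 0
      } else {
        alpha_new <- num / ((npairs - p) * phi)
        max_ni <- max(lengths(idx))
        alpha_new <- max(min(alpha_new, 0.95),
                         -0.95 / max(1, max_ni - 1))  # keep V positive definite
      }
      # damped moment update; with very few within-cluster pairs the raw
      # update can cycle between clamped values. Past 60% of the budget the
      # working correlation is frozen, after which the (linear) beta step
      # closes in a single iteration.
      if (it <= 0.6 * maxit) {
        d_alpha <- 0.5 * (alpha_new - alpha)
        alpha <- alpha + d_alpha
      }
    }
    A <- matrix(0, p, p); b <- numeric(p)
    for (ix in idx) {
      ni <- length(ix)
      Xi <- X[ix, , drop = FALSE]; yi <- y[ix]
      Vinv <- solve((1 - alpha) * diag(ni) + alpha * matrix(1, ni, ni))
      A <- A + crossprod(Xi, Vinv %*% Xi)
      b <- b + crossprod(Xi, Vinv %*% yi)
    }
    beta_new <- solve(A, b)
    delta <- max(abs(beta_new - beta))
    trace <- c(trace, delta)
    beta <- beta_new
    if (delta < tol && abs(d_alpha) < 1e-6) break
  }
  if (trace[length(trace)] >= tol)
    stop("GEE did not converge in ", maxit, " iterations; |delta beta| trace: ",
         paste(signif(utils::tail(trace, 5L), 3), collapse = ", "))

  # cluster-level sandwich
  e <- y - as.numeric(X %*% beta)
  A <- matrix(0, p, p); B <- matrix(0, p, p)
  for (ix in idx) {
    ni <- length(ix)
    Xi <- X[ix, , drop = FALSE]; ei <- e[ix]
    Vinv <- solve((1 - alpha) * diag(ni) + alpha * matrix(1, ni, ni))
    XtVi <- crossprod(Xi, Vinv)
    A <- A + XtVi %*% Xi
    u <- XtVi %*% ei
    B <- B + tcrossprod(u)
  }
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv
  dimnames(V) <- list(colnames(X), colnames(X))
  beta <- setNames(as.numeric(beta), colnames(X))
  se <- sqrt(diag(V))
  z <- beta / se
  pv <- 2 * pnorm(-abs(z))

  keep_coef <- setdiff(colnames(X), "(Intercept)")
  structure(
    list(coefficients = beta[keep_coef], intercept = beta[["(Intercept)"]],
         robust_se = se[keep_coef], wald_z = z[keep_coef],
         p_values = pv[keep_coef],
         vcov_robust = V[keep_coef, keep_coef, drop = FALSE],
         vcov_full = V, reference = ref_level,
         working_correlation = working_correlation, alpha = alpha,
         dispersion = sum(e^2) / (n - p), n_obs = n,
         n_clusters = length(idx), iterations = it),
    class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("Gaussian GEE (%s working correlation), %d obs in %d clusters\n",
              x$working_correlation, x$n_obs, x$n_clusters))
  if (!is.na(x$reference)) cat("  reference level:", x$reference, "\n")
  tab <- data.frame(estimate = x$coefficients, robust_se = x$robust_se,
                    z = x$wald_z, p = x$p_values)
  print(tab, digits = 4)
  invisible(x)
}

#' Joint Wald chi-squared test over a fit's coefficients
#'
#' Post-estimation test of the combined null that all non-reference
#' coefficients of a GEE fit are zero, using the robust covariance:
#' `chi2 = beta' V^-1 beta` on as many degrees of freedom as coefficients
#' tested. With a single coefficient this reduces to the square of the Wald
#' z statistic.
#'
#' @param fit a `"gee_fit"`.
#' @return an object of class `"joint_test"`: a list with `chi2`, `df`,
#'   `p_value`.
#' @export
joint_wald_test <- function(fit) {
  stopifnot(inherits(fit, "gee_fit"))
  beta <- fit$coefficients
  V <- fit$vcov_robust
  if (length(beta) < 1L) stop("fit has no testable coefficients")
  Vinv <- tryCatch(solve(V), error = function(e)
    stop("singular robust covariance; joint test undefined"))
  chi2 <- as.numeric(t(beta) %*% Vinv %*% beta)
  df <- length(beta)
  structure(list(chi2 = chi2, df = df,
                 p_value = pchisq(chi2, df, lower.tail = FALSE)),
            class = "joint_test")
}

#' @export
print.joint_test <- function(x, ...) {
  cat(sprintf("Joint Wald test: chi2 = %.4g on %d df, p = %.4g\n",
              x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Fit the per-comparison GEE models for a study
#'
#' One univariable Gaussian GEE per grader-by-device comparison and
#' predictor, clustered by patient — the study's inferential surface. For
#' pigmentation the reference level is `"pigmented"`, so coefficients are
#' delta-mean HD95 of nonpigmented and mixed-pigmented lesions versus
#' pigmented ones; multi-level predictors additionally get the joint Wald
#' chi-squared test.
#'
#' @param records agreement records (see [evaluate_agreement()]).
#' @param meta per-lesion metadata (see [read_lesion_meta()]).
#' @param predictors character vector of `meta` column names to model.
#' @param comparisons which comparisons to model (default: the four
#'   unimodal-vs-multimodal ones).
#' @param working_correlation passed to [fit_gaussian_gee()].
#' @return a data.frame with one row per comparison x predictor x level:
#'   estimate, robust SE, z, p, and the joint test where applicable; the
#'   fitted objects are attached as attribute `"fits"`.
#' @export
run_gee_models <- function(records, meta, predictors = "pigmentation",
                           comparisons = COMPARISONS[1:4],
                           working_correlation = "exchangeable") {
  records <- as.data.frame(records)
  meta <- as.data.frame(meta)
  rows <- list(); fits <- list()
  for (cmp in comparisons) {
    rec <- records[records$comparison == cmp, ]
    m <- merge(rec, meta, by = "lesion_id", sort = TRUE)
    for (pred in predictors) {
      ref <- if (pred == "pigmentation") "pigmented" else NULL
      fit <- fit_gaussian_gee(m$hd95_mm, m[[pred]], m$patient_id,
                              reference = ref,
                              working_correlation = working_correlation)
      fits[[paste(cmp, pred, sep = ".")]] <- fit
      jt <- if (length(fit$coefficients) >= 2L) joint_wald_test(fit) else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = cmp, predictor = pred,
        level = names(fit$coefficients),
        estimate = unname(fit$coefficients),
        robust_se = unname(fit$robust_se),
        wald_z = unname(fit$wald_z), p_value = unname(fit$p_values),
        joint_chi2 = if (is.null(jt)) NA_real_ else jt$chi2,
        joint_df = if (is.null(jt)) NA_integer_ else jt$df,
        joint_p = if (is.null(jt)) NA_real_ else jt$p_value,
        n_obs = fit$n_obs, n_clusters = fit$n_clusters)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}
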