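# Heterogeneity, horizontal-pleiotropy and directionality diagnostics.

#' Cochran's Q heterogeneity test
#'
#' `Q = sum_j w_j (theta_j - theta_hat)^2` over per-SNP Wald ratios with
#' inverse-variance weights `w_j = bx_j^2 / sey_j^2`, referred to a
#' chi-square distribution with J - 1 degrees of freedom. Q is minimized at
#' the fixed-effect IVW estimate, the default reference point.
#'
#' @param instr A `"harmonized_set"` with at least two instruments.
#' @param theta_hat Reference causal estimate; defaults to the IVW estimate.
#' @return List with `q`, `df`, `pval`.
#' @export
cochran_q <- function(instr, theta_hat = NULL) {
  J <- n_snp(instr)
  if (J < 2) stop("Cochran's Q requires at least 2 instruments")
  rs <- ratio_stats(instr)
  if (is.null(theta_hat)) theta_hat <- sum(rs$w * rs$theta) / sum(rs$w)
  q <- sum(rs$w * (rs$theta - theta_hat)^2)
  list(q = q, df = J - 1L,
       pval = stats::pchisq(q, J - 1, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Extracts the intercept of the MR-Egger fit and its two-sided t-test
#' (J - 2 df). A small p-value indicates directional pleiotropy.
#'
#' @param instr A `"harmonized_set"` with at least three instruments.
#' @return List with `intercept`, `se`, `pval`.
#' @export
egger_intercept_test <- function(instr) {
  e <- mr_egger(instr)$extra
  list(intercept = e$intercept, se = e$intercept_se, pval = e$intercept_pval)
}

ivw_point <- function(bx, by, sey) {
  sum(bx * by / sey^2) / sum(bx^2 / sey^2)
}

loo_theta <- function(bx, by, sey) {
  num <- bx * by / sey^2
  den <- bx^2 / sey^2
  (sum(num) - num) / (sum(den) - den)
}

#' MR-PRESSO: global pleiotropy, outlier and distortion tests
#'
#' The three-step residual-sum-of-squares procedure. (1) Global test: the
#' observed weighted RSS of leave-one-out IVW predictions is compared with
#' its parametric null distribution, obtained by simulating instrument sets
#' with no pleiotropy (`by_j ~ N(theta_(-j) bx_j, sey_j)`,
#' `bx_j ~ N(bx_j, sex_j)`); the p-value is the rank-based exceedance
#' probability with +1 smoothing. (2) Outlier test: each SNP's observed
#' squared residual is compared with its simulated distribution; per-SNP
#' p-values are Bonferroni-adjusted across instruments and SNPs with
#' adjusted p below `alpha` are flagged. (3) Distortion test: the relative
#' difference between the IVW estimates before and after outlier removal is
#' compared with the distribution of the same quantity under random removal
#' of equally many SNPs.
#'
#' @param instr A `"harmonized_set"` with at least four instruments.
#' @param n_sim Number of parametric simulations (default 1000, min 100).
#' @param seed Seed for the simulations (required: the rank-based p-value is
#'   bit-reproducible for a fixed seed).
#' @param alpha Significance level for the outlier test (default 0.05).
#' @return List with `global_pval`, `outliers` (SNP ids), `outlier_pvals`
#'   (Bonferroni-adjusted, named), `distortion_pval` (NA when no outliers),
#'   and `corrected_estimate` (IVW on the outlier-free set).
#' @export
mr_presso <- function(instr, n_sim = 1000, seed = 1, alpha = 0.05) {
  J <- n_snp(instr)
  if (J < 4) stop("MR-PRESSO requires at least 4 instruments")
  if (n_sim < 100) stop("n_sim must be at least 100")
  bx <- instr$beta_exp
  by <- instr$beta_out
  sex <- instr$se_exp
  sey <- instr$se_out

  th_loo <- loo_theta(bx, by, sey)
  res_obs <- (by - th_loo * bx)^2 / sey^2
  rss_obs <- sum(res_obs)

  set.seed(seed)
  bx_sim <- matrix(stats::rnorm(n_sim * J, rep(bx, each = n_sim),
                                rep(sex, each = n_sim)), n_sim, J)
  by_sim <- matrix(stats::rnorm(n_sim * J, rep(th_loo * bx, each = n_sim),
                                rep(sey, each = n_sim)), n_sim, J)
  sey2 <- matrix(sey^2, n_sim, J, byrow = TRUE)
  num <- bx_sim * by_sim / sey2
  den <- bx_sim^2 / sey2
  th_loo_sim <- (rowSums(num) - num) / (rowSums(den) - den)
  res_sim <- (by_sim - th_loo_sim * bx_sim)^2 / sey2
  rss_sim <- rowSums(res_sim)

  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  p_out <- (1 + colSums(res_sim >= rep(res_obs, each = n_sim))) / (n_sim + 1)
  p_adj <- pmin(1, p_out * J)
  names(p_adj) <- instr$snp_id
  outliers <- instr$snp_id[p_adj < alpha]

  theta_all <- ivw_point(bx, by, sey)
  if (length(outliers) == J) {
    stop(structure(class = c("mrpath_degenerate_correction", "error", "condition"),
                   list(message = "MR-PRESSO flagged every instrument as an outlier",
                        call = sys.call())))
  }
  keep <- !(instr$snp_id %in% outliers)
  corrected <- ivw_random_effects(subset_instruments(instr, keep))
  distortion_pval <- NA_real_
  if (length(outliers) > 0) {
    k <- length(outliers)
    d_obs <- (corrected$beta - theta_all) / abs(theta_all) * 100
    d_null <- vapply(seq_len(n_sim), function(b) {
      drop <- sample.int(J, k)
      (ivw_point(bx[-drop], by[-drop], sey[-drop]) - theta_all) /
        abs(theta_all) * 100
    }, numeric(1))
    distortion_pval <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
  }
  list(global_pval = global_pval, outliers = outliers, outlier_pvals = p_adj,
       distortion_pval = distortion_pval, corrected_estimate = corrected)
}

subset_instruments <- function(instr, keep) {
  out <- instr
  for (f in c("snp_id", "beta_exp", "se_exp", "beta_out", "se_out",
              "eaf", "flipped")) {
    out[[f]] <- instr[[f]][keep]
  }
  out
}

#' Steiger directionality test
#'
#' Compares the variance in the exposure explained by the instruments with
#' the variance explained in the outcome, using the t-statistic-based
#' approximation `r2 = sum_j t_j^2 / (t_j^2 + n - 2)` per trait. The causal
#' direction is called correct when the instruments explain more of the
#' exposure. The p-value is a two-sample z-test on the Fisher-transformed
#' pooled correlations with the respective sample sizes. For binary outcomes
#' the same approximation is applied on the log-odds scale.
#'
#' @param instr A `"harmonized_set"`.
#' @param n_exp,n_out Sample sizes (default: taken from `instr`).
#' @return List with `correct_direction`, `r2_exp`, `r2_out`, `pval`.
#' @export
steiger_direction <- function(instr, n_exp = instr$n_exp, n_out = instr$n_out) {
  stopifnot(n_exp > 10, n_out > 10)
  t_exp <- instr$beta_exp / instr$se_exp
  t_out <- instr$beta_out / instr$se_out
  r2_exp <- min(sum(t_exp^2 / (t_exp^2 + n_exp - 2)), 1 - 1e-12)
  r2_out <- min(sum(t_out^2 / (t_out^2 + n_out - 2)), 1 - 1e-12)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  list(correct_direction = r2_exp > r2_out,
       r2_exp = r2_exp, r2_out = r2_out,
       pval = 2 * stats::pnorm(-abs(z)))
}

#' Full sensitivity battery for one exposure-outcome pair
#'
#' Runs Cochran's Q (at the IVW estimate), the MR-Egger intercept test, the
#' MR-PRESSO three-step procedure (when at least four instruments are
#' available) and the Steiger directionality test, and assembles them into a
#' single report.
#'
#' @param instr A `"harmonized_set"` with at least two instruments.
#' @param n_sim,seed,alpha Passed to [mr_presso()].
#' @return A list with class `"sensitivity_report"`: `q`, `q_df`, `q_pval`,
#'   `egger_intercept`, `egger_intercept_se`, `egger_intercept_pval`,
#'   `presso_global_pval`, `presso_outliers`, `presso_distortion_pval`,
#'   `steiger_correct_direction`, `steiger_pval`. Components whose
#'   instrument-count preconditions fail are NA.
#' @export
sensitivity_report <- function(instr, n_sim = 1000, seed = 1, alpha = 0.05) {
  J <- n_snp(instr)
  qres <- cochran_q(instr)
  eg <- if (J >= 3) {
    egger_intercept_test(instr)
  } else {
    list(intercept = NA_real_, se = NA_real_, pval = NA_real_)
  }
  pr <- if (J >= 4) {
    mr_presso(instr, n_sim = n_sim, seed = seed, alpha = alpha)
  } else {
    list(global_pval = NA_real_, outliers = character(),
         distortion_pval = NA_real_)
  }
  st <- if (!is.na(instr$n_exp) && !is.na(instr$n_out)) {
    steiger_direction(instr)
  } else {
    list(correct_direction = NA, pval = NA_real_)
  }
  structure(list(
    q = qres$q, q_df = qres$df, q_pval = qres$pval,
    egger_intercept = eg$intercept, egger_intercept_se = eg$se,
    egger_intercept_pval = eg$pval,
    presso_global_pval = pr$global_pval,
    presso_outliers = pr$outliers,
    presso_distortion_pval = pr$distortion_pval,
    steiger_correct_direction = st$correct_direction,
    steiger_pval = st$pval
  ), class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Q=%.3f (df=%d, p=%.3g); Egger intercept p=%.3g; PRESSO global p=%.3g; Steiger correct=%s\n",
              x$q, x$q_df, x$q_pval, x$egger_intercept_pval,
              x$presso_global_pval, x$steiger_correct_direction))
  invisible(x)
}

#' Heterogeneity/pleiotropy exclusion rule
#'
#' The gate applied before multivariable model averaging: an exposure is
#' flagged (and excluded) when Cochran's Q, the Egger intercept test or the
#' MR-PRESSO global test is significant at `alpha`. Diagnostics that could
#' not be computed (NA) do not trigger the flag.
#'
#' @param report A `"sensitivity_report"`.
#' @param alpha Significance level (default 0.05).
#' @return `TRUE` when heterogeneity or horizontal pleiotropy is present.
#' @export
flag_het_pleio <- function(report, alpha = 0.05) {
  isTRUE(report$q_pval < alpha) ||
    isTRUE(report$egger_intercept_pval < alpha) ||
    isTRUE(report$presso_global_pval < alpha)
}
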