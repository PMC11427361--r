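# Univariate two-sample MR estimators.
#
# All estimators work on per-SNP Wald ratios theta_j = beta_out_j / beta_exp_j
# with first-order weights w_j = beta_exp_j^2 / se_out_j^2 (equivalently,
# weighted regression of beta_out on beta_exp with weights 1/se_out^2).

mr_estimate <- function(method, beta, se, pval, n_snp, extra = list()) {
  structure(list(
    method = method, beta = beta, se = se, pval = pval,
    or_ = exp(beta), ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se), n_snp = n_snp, extra = extra
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%s (%d SNPs): beta=%.*f se=%.*f OR=%.2f [%.2f, %.2f] p=%.3g\n",
              x$method, x$n_snp, digits, x$beta, digits, x$se,
              x$or_, x$ci_low, x$ci_high, x$pval))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snp, beta = x$beta, se = x$se,
             pval = x$pval, or = x$or_, ci_low = x$ci_low, ci_high = x$ci_high,
             stringsAsFactors = FALSE)
}

ratio_stats <- function(instr) {
  list(theta = instr$beta_out / instr$beta_exp,
       w = instr$beta_exp^2 / instr$se_out^2)
}

#' Wald ratio estimate for a single instrument
#'
#' Causal effect `by/bx` with first-order delta-method standard error
#' `sey/|bx|` (the uncertainty in the SNP-exposure effect is ignored, the
#' dominant convention for strong instruments; see `second_order`).
#'
#' @param bx,sex SNP-exposure effect and its standard error.
#' @param by,sey SNP-outcome effect and its standard error.
#' @param second_order If `TRUE`, use the second-order delta variance
#'   `sey^2/bx^2 + by^2 sex^2 / bx^4`.
#' @return An `"mr_estimate"` with method `"wald_ratio"`.
#' @export
#' @examples
#' wald_ratio(0.1, 0.01, 0.2, 0.05) # beta 2, se 0.5
wald_ratio <- function(bx, sex, by, sey, second_order = FALSE) {
  if (bx == 0) stop("Wald ratio undefined: SNP-exposure effect is zero")
  beta <- by / bx
  se <- if (second_order) {
    sqrt(sey^2 / bx^2 + by^2 * sex^2 / bx^4)
  } else {
    sey / abs(bx)
  }
  p <- 2 * stats::pnorm(-abs(beta / se))
  mr_estimate("wald_ratio", beta, se, p, 1L)
}

#' Random-effects inverse-variance-weighted estimate
#'
#' Precision-weighted average of per-SNP Wald ratios; identical to weighted
#' least squares of the outcome effects on the exposure effects through the
#' origin with weights `1/se_out^2`. The standard error is the fixed-effect
#' one inflated multiplicatively by `sqrt(Q/(J-1))`, floored at 1, so the
#' random-effects interval never shrinks below the fixed-effect interval.
#' Inference is normal-theory, two-sided.
#'
#' @param instr A `"harmonized_set"` with at least two instruments.
#' @return An `"mr_estimate"` with method `"ivw_re"`; `extra` carries
#'   Cochran's `Q`, its df and p, and the fixed-effect se.
#' @export
ivw_random_effects <- function(instr) {
  J <- n_snp(instr)
  if (J < 2) {
    stop("IVW requires at least 2 instruments; use wald_ratio() for a single SNP")
  }
  rs <- ratio_stats(instr)
  theta <- sum(rs$w * rs$theta) / sum(rs$w)
  se_fixed <- 1 / sqrt(sum(rs$w))
  q <- sum(rs$w * (rs$theta - theta)^2)
  scale <- max(1, sqrt(q / (J - 1)))
  se <- se_fixed * scale
  p <- 2 * stats::pnorm(-abs(theta / se))
  mr_estimate("ivw_re", theta, se, p, J,
              extra = list(q = q, q_df = J - 1L,
                           q_pval = stats::pchisq(q, J - 1, lower.tail = FALSE),
                           se_fixed = se_fixed))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with an
#' intercept, weights `1/se_out^2`. Exposure effects are oriented
#' non-negative (flipping the outcome effect in tandem) before fitting, so
#' the intercept estimates the average directional pleiotropy. The slope is
#' the causal estimate. Inference uses the t-distribution with J - 2 df from
#' the standard weighted-least-squares fit.
#'
#' @param instr A `"harmonized_set"` with at least three instruments.
#' @return An `"mr_estimate"` with method `"egger"`; `extra` carries
#'   `intercept`, `intercept_se`, `intercept_pval` and the residual dispersion
#'   `sigma`.
#' @export
mr_egger <- function(instr) {
  J <- n_snp(instr)
  if (J < 3) stop("MR-Egger requires at least 3 instruments")
  s <- sign(instr$beta_exp)
  s[s == 0] <- 1
  bx <- instr$beta_exp * s
  by <- instr$beta_out * s
  w <- 1 / instr$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  cf <- sm$coefficients
  slope <- cf["bx", "Estimate"]
  slope_se <- cf["bx", "Std. Error"]
  int <- cf["(Intercept)", "Estimate"]
  int_se <- cf["(Intercept)", "Std. Error"]
  # numerically perfect fits leave 0/0 t-statistics; resolve them by the
  # size of the estimate relative to the data scale
  if (sm$sigma < 1e-10 * max(abs(by), 1)) {
    tol <- 1e-10 * max(abs(by), 1)
    slope_t <- if (abs(slope) < tol) 0 else Inf
    int_t <- if (abs(int) < tol) 0 else Inf
  } else {
    slope_t <- slope / slope_se
    int_t <- int / int_se
  }
  p <- 2 * stats::pt(-abs(slope_t), df = J - 2)
  int_p <- 2 * stats::pt(-abs(int_t), df = J - 2)
  mr_estimate("egger", slope, slope_se, p, J,
              extra = list(intercept = int, intercept_se = int_se,
                           intercept_pval = int_p,
                           sigma = summary(fit)$sigma))
}

weighted_median_point <- function(theta, w) {
  w <- w / sum(w)
  o <- order(theta)
  theta <- theta[o]
  w <- w[o]
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(theta[1])
  if (s[length(s)] < 0.5) return(theta[length(theta)])
  k <- max(which(s < 0.5))
  theta[k] + (theta[k + 1] - theta[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

boot_se <- function(instr, point_fun, n_boot, seed) {
  if (!is.null(seed)) set.seed(seed)
  J <- n_snp(instr)
  est <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(J, instr$beta_exp, instr$se_exp)
    by <- stats::rnorm(J, instr$beta_out, instr$se_out)
    point_fun(by / bx, bx^2 / instr$se_out^2)
  }, numeric(1))
  stats::sd(est)
}

#' Weighted median estimate
#'
#' The inverse-variance-weighted median of the per-SNP Wald ratios: ratios
#' are ordered and the estimate is the value at cumulative normalized weight
#' 0.5, linearly interpolated. Consistent when at least half the weight comes
#' from valid instruments. The standard error is a seeded parametric
#' bootstrap (per-SNP betas resampled from their normal sampling
#' distributions).
#'
#' @param instr A `"harmonized_set"` with at least three instruments.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap (required for reproducibility).
#' @return An `"mr_estimate"` with method `"weighted_median"`.
#' @export
weighted_median <- function(instr, n_boot = 1000, seed = 1) {
  J <- n_snp(instr)
  if (J < 3) stop("weighted median requires at least 3 instruments")
  rs <- ratio_stats(instr)
  beta <- weighted_median_point(rs$theta, rs$w)
  se <- boot_se(instr, weighted_median_point, n_boot, seed)
  p <- 2 * stats::pnorm(-abs(beta / se))
  mr_estimate("weighted_median", beta, se, p, J)
}

mode_point <- function(theta, w, phi) {
  w <- w / sum(w)
  m <- sum(w * theta)
  s <- sqrt(sum(w * (theta - m)^2))
  if (s <= max(abs(theta), 1) * 1e-10) return(m)
  h <- phi * 1.06 * s * length(theta)^(-1 / 5)
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = 4096)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm(x, theta, h)), numeric(1))
  best <- grid[which.max(dens)]
  step <- grid[2] - grid[1]
  stats::optimize(function(x) sum(w * stats::dnorm(x, theta, h)),
                  lower = best - step, upper = best + step,
                  maximum = TRUE)$maximum
}

#' Mode-based estimate (simple or weighted)
#'
#' The mode of the kernel-smoothed density of per-SNP Wald ratios (normal
#' kernel). The bandwidth is `phi * 1.06 * s * J^(-1/5)` with `s` the
#' (weighted) standard deviation of the ratios. The simple mode uses equal
#' weights; the weighted mode uses inverse-variance weights. Consistent under
#' the ZEMPA assumption that the largest group of instruments share the true
#' ratio. Bootstrap standard error as in [weighted_median()].
#'
#' @param instr A `"harmonized_set"` with at least three instruments.
#' @param weighted Use inverse-variance weights (`TRUE`) or equal weights.
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap.
#' @return An `"mr_estimate"` with method `"weighted_mode"` or
#'   `"simple_mode"`.
#' @export
mode_estimate <- function(instr, weighted = TRUE, phi = 1,
                          n_boot = 1000, seed = 1) {
  J <- n_snp(instr)
  if (J < 3) stop("mode estimator requires at least 3 instruments")
  stopifnot(phi > 0)
  rs <- ratio_stats(instr)
  wts <- if (weighted) rs$w else rep(1, J)
  beta <- mode_point(rs$theta, wts, phi)
  pf <- if (weighted) {
    function(theta, w) mode_point(theta, w, phi)
  } else {
    function(theta, w) mode_point(theta, rep(1, length(theta)), phi)
  }
  se <- boot_se(instr, pf, n_boot, seed)
  p <- 2 * stats::pnorm(-abs(beta / se))
  mr_estimate(if (weighted) "weighted_mode" else "simple_mode", beta, se, p, J)
}

#' Run every applicable univariate MR estimator
#'
#' Dispatch follows instrument count: a single SNP yields only the Wald
#' ratio; two SNPs yield the random-effects IVW; three or more additionally
#' yield MR-Egger, weighted median, and the simple and weighted modes.
#' Methods that cannot run are recorded with a reason.
#'
#' @param instr A non-empty `"harmonized_set"`.
#' @param n_boot,seed,phi Passed to the bootstrap-based estimators.
#' @return A data frame with one row per estimate (`method`, `n_snp`, `beta`,
#'   `se`, `pval`, `or`, `ci_low`, `ci_high`); the `"skipped"` attribute is a
#'   data frame of methods not run and why.
#' @export
estimate_all <- function(instr, n_boot = 1000, seed = 1, phi = 1) {
  J <- n_snp(instr)
  if (J < 1) stop("empty instrument set")
  ests <- list()
  skipped <- data.frame(method = character(), reason = character(),
                        stringsAsFactors = FALSE)
  skip <- function(m, why) {
    skipped <<- rbind(skipped, data.frame(method = m, reason = why,
                                          stringsAsFactors = FALSE))
  }
  if (J == 1) {
    ests$wald <- wald_ratio(instr$beta_exp, instr$se_exp,
                            instr$beta_out, instr$se_out)
    for (m in c("ivw_re", "egger", "weighted_median",
                "simple_mode", "weighted_mode")) {
      skip(m, "fewer than 2 SNPs")
    }
  } else {
    skip("wald_ratio", "more than 1 SNP")
    ests$ivw <- ivw_random_effects(instr)
    if (J >= 3) {
      ests$egger <- mr_egger(instr)
      ests$wm <- weighted_median(instr, n_boot, seed)
      ests$sm <- mode_estimate(instr, weighted = FALSE, phi, n_boot, seed)
      ests$wmode <- mode_estimate(instr, weighted = TRUE, phi, n_boot, seed)
    } else {
      for (m in c("egger", "weighted_median", "simple_mode", "weighted_mode")) {
        skip(m, "fewer than 3 SNPs")
      }
    }
  }
  out <- do.call(rbind, lapply(ests, as.data.frame))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
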