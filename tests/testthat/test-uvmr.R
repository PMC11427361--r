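test_that("Wald ratio arithmetic, null case and sign antisymmetry", {
  est <- wald_ratio(0.1, 0.01, 0.2, 0.05)
  expect_equal(est$beta, 2)
  expect_equal(est$se, 0.5)
  expect_equal(est$or_, exp(2))
  null <- wald_ratio(0.1, 0.01, 0, 0.05)
  expect_equal(null$beta, 0)
  expect_equal(null$pval, 1)
  neg <- wald_ratio(-0.1, 0.01, 0.2, 0.05)
  expect_equal(neg$beta, -2)
  expect_equal(neg$se, 0.5)
  expect_error(wald_ratio(0, 0.01, 0.2, 0.05), "zero")
  # second-order delta variance dominates the first-order one
  expect_gt(wald_ratio(0.1, 0.05, 0.2, 0.05, second_order = TRUE)$se, est$se)
})

test_that("homogeneous ratios collapse every estimator to the common ratio", {
  set.seed(3)
  bx <- runif(10, 0.05, 0.3) * sample(c(-1, 1), 10, replace = TRUE)
  instr <- make_instr(bx, 0.5 * bx, sey = runif(10, 0.01, 0.05))
  ivw <- ivw_random_effects(instr)
  expect_equal(ivw$beta, 0.5, tolerance = 1e-12)
  expect_equal(ivw$extra$q, 0, tolerance = 1e-12)
  expect_equal(ivw$se, ivw$extra$se_fixed)
  eg <- mr_egger(instr)
  expect_equal(eg$beta, 0.5, tolerance = 1e-8)
  expect_equal(eg$extra$intercept, 0, tolerance = 1e-8)
  expect_equal(weighted_median(instr)$beta, 0.5, tolerance = 1e-12)
  expect_equal(mode_estimate(instr, weighted = TRUE)$beta, 0.5, tolerance = 1e-6)
  expect_equal(mode_estimate(instr, weighted = FALSE)$beta, 0.5, tolerance = 1e-6)
})

test_that("IVW equals the weighted-least-squares-through-origin oracle", {
  set.seed(11)
  for (rep in 1:20) {
    J <- sample(2:30, 1)
    bx <- rnorm(J, 0, 0.2)
    bx[abs(bx) < 0.01] <- 0.05
    by <- rnorm(J, 0.3 * bx, 0.02)
    sey <- runif(J, 0.005, 0.05)
    instr <- make_instr(bx, by, sey = sey)
    expect_equal(ivw_random_effects(instr)$beta,
                 wls_origin_oracle(bx, by, sey), tolerance = 1e-10)
  }
  instr2 <- make_instr(c(0.1, 0.2), c(0.05, 0.08), sey = c(0.01, 0.03))
  expect_equal(ivw_random_effects(instr2)$beta,
               wls_origin_oracle(c(0.1, 0.2), c(0.05, 0.08), c(0.01, 0.03)),
               tolerance = 1e-10)
  expect_error(ivw_random_effects(make_instr(0.1, 0.2)), "at least 2")
})

test_that("estimators are equivariant under joint per-SNP sign flips", {
  set.seed(21)
  J <- 9
  bx <- rnorm(J, 0.2, 0.05)
  by <- rnorm(J, 0.3 * bx, 0.02)
  sey <- runif(J, 0.01, 0.04)
  s <- sample(c(-1, 1), J, replace = TRUE)
  a <- make_instr(bx, by, sey = sey)
  b <- make_instr(s * bx, s * by, sey = sey)
  expect_equal(ivw_random_effects(b)$beta, ivw_random_effects(a)$beta,
               tolerance = 1e-12)
  expect_equal(mr_egger(b)$beta, mr_egger(a)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(b)$extra$intercept, mr_egger(a)$extra$intercept,
               tolerance = 1e-12)
  expect_equal(weighted_median(b, seed = 1)$beta,
               weighted_median(a, seed = 1)$beta, tolerance = 1e-12)
  expect_equal(mode_estimate(b, seed = 1)$beta,
               mode_estimate(a, seed = 1)$beta, tolerance = 1e-9)
})

test_that("MR-Egger recovers exact linear and affine relations", {
  bx <- c(0.1, 0.15, 0.2, 0.25, 0.3)
  instr <- make_instr(bx, 0.4 * bx)
  fit <- mr_egger(instr)
  expect_equal(fit$beta, 0.4, tolerance = 1e-10)
  expect_equal(fit$extra$intercept, 0, tolerance = 1e-10)
  instr2 <- make_instr(bx, 0.1 + 0.4 * bx)
  fit2 <- mr_egger(instr2)
  expect_equal(fit2$beta, 0.4, tolerance = 1e-10)
  expect_equal(fit2$extra$intercept, 0.1, tolerance = 1e-10)
  expect_error(mr_egger(make_instr(c(0.1, 0.2), c(0.1, 0.2))), "at least 3")
})

test_that("MR-Egger intercept recovers directional pleiotropy in simulation", {
  set.seed(31)
  reps <- 300
  J <- 20
  ints <- vapply(seq_len(reps), function(r) {
    bx <- runif(J, 0.1, 0.4)
    alpha <- rnorm(J, 0.05, 0.01)
    sey <- rep(0.02, J)
    by <- 0.3 * bx + alpha + rnorm(J, 0, sey)
    mr_egger(make_instr(bx, by, sey = sey))$extra$intercept
  }, numeric(1))
  mc_se <- sd(ints) / sqrt(reps)
  expect_lt(abs(mean(ints) - 0.05), 2 * mc_se + 1e-12)
})

test_that("weighted median matches the cumulative-weight interpolation oracle", {
  expect_equal(mrpath:::weighted_median_point(c(1, 2, 3), c(1, 1, 1)), 2)
  expect_equal(mrpath:::weighted_median_point(c(1, 2, 3), c(0.1, 0.8, 0.1)), 2)
  set.seed(41)
  for (rep in 1:10) {
    theta <- rnorm(7)
    w <- runif(7, 0.1, 2)
    expect_equal(mrpath:::weighted_median_point(theta, w),
                 cumweight_median_oracle(theta, w), tolerance = 1e-10)
  }
  # full estimator path on a random instrument set
  bx <- runif(7, 0.1, 0.3)
  by <- rnorm(7, 0.2 * bx, 0.02)
  sey <- runif(7, 0.01, 0.03)
  est <- weighted_median(make_instr(bx, by, sey = sey), seed = 7)
  expect_equal(est$beta, cumweight_median_oracle(by / bx, bx^2 / sey^2),
               tolerance = 1e-10)
  expect_gt(est$se, 0)
})

test_that("mode estimators match the dense-grid KDE oracle", {
  instr <- make_instr(c(0.1, 0.2, 0.3, 0.1), c(0.1, 0.2, 0.3, 0.5))
  est <- mode_estimate(instr, weighted = FALSE, seed = 1)
  expect_equal(est$beta, 1.0, tolerance = 0.3) # dominant cluster at ratio 1
  same <- make_instr(c(0.1, 0.2, 0.3), c(0.07, 0.14, 0.21))
  expect_equal(mode_estimate(same, seed = 1)$beta, 0.7, tolerance = 1e-9)
  set.seed(51)
  bx <- runif(9, 0.1, 0.4)
  by <- rnorm(9, 0.25 * bx, 0.03)
  sey <- runif(9, 0.01, 0.05)
  theta <- by / bx
  for (weighted in c(TRUE, FALSE)) {
    w <- if (weighted) bx^2 / sey^2 else rep(1, 9)
    est <- mode_estimate(make_instr(bx, by, sey = sey), weighted = weighted,
                         seed = 2)
    expect_equal(est$beta, grid_kde_mode_oracle(theta, w), tolerance = 1e-3)
  }
})

test_that("estimate_all dispatches on instrument count with recorded skips", {
  one <- make_instr(0.1, 0.05)
  res1 <- estimate_all(one)
  expect_equal(res1$method, "wald_ratio")
  expect_true("ivw_re" %in% attr(res1, "skipped")$method)

  two <- make_instr(c(0.1, 0.2), c(0.05, 0.1))
  res2 <- estimate_all(two)
  expect_equal(res2$method, "ivw_re")
  sk <- attr(res2, "skipped")
  expect_equal(sk$reason[sk$method == "egger"], "fewer than 3 SNPs")

  set.seed(61)
  bx <- runif(10, 0.1, 0.4)
  res10 <- estimate_all(make_instr(bx, 0.3 * bx), seed = 3)
  expect_setequal(res10$method, c("ivw_re", "egger", "weighted_median",
                                  "simple_mode", "weighted_mode"))
  expect_equal(res10$beta, rep(0.3, 5), tolerance = 1e-6)
  expect_true(all(res10$or >= res10$ci_low & res10$or <= res10$ci_high))
  expect_error(estimate_all(make_instr(numeric(), numeric())))
})
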