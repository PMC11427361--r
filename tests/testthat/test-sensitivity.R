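test_that("Cochran's Q: homogeneity, hand computation, and minimization at IVW", {
  set.seed(3)
  bx <- runif(6, 0.1, 0.3)
  hom <- make_instr(bx, 0.4 * bx, sey = runif(6, 0.01, 0.03))
  q0 <- cochran_q(hom)
  expect_equal(q0$q, 0, tolerance = 1e-12)
  expect_equal(q0$pval, 1)
  expect_equal(q0$df, 5)

  # two-instrument symbolic check
  bx2 <- c(0.1, 0.2); by2 <- c(0.05, 0.12); sey2 <- c(0.02, 0.03)
  w <- bx2^2 / sey2^2
  th <- c(0.05 / 0.1, 0.12 / 0.2)
  th_hat <- sum(w * th) / sum(w)
  q_hand <- w[1] * (th[1] - th_hat)^2 + w[2] * (th[2] - th_hat)^2
  got <- cochran_q(make_instr(bx2, by2, sey = sey2))
  expect_equal(got$q, q_hand, tolerance = 1e-12)
  expect_equal(got$pval, pchisq(q_hand, 1, lower.tail = FALSE))

  # Q at the fixed-effect IVW estimate is a minimum over nearby theta
  set.seed(5)
  bx3 <- runif(8, 0.1, 0.4)
  by3 <- rnorm(8, 0.3 * bx3, 0.03)
  instr <- make_instr(bx3, by3, sey = rep(0.03, 8))
  th_ivw <- ivw_random_effects(instr)$beta
  q_min <- cochran_q(instr, th_ivw)$q
  for (eps in c(1e-3, 1e-2, 0.1)) {
    expect_gte(cochran_q(instr, th_ivw + eps)$q, q_min)
    expect_gte(cochran_q(instr, th_ivw - eps)$q, q_min)
  }
})

test_that("Egger intercept test flags constructed pleiotropy and not exact proportionality", {
  bx <- c(0.1, 0.15, 0.2, 0.25, 0.3, 0.35)
  clean <- egger_intercept_test(make_instr(bx, 0.4 * bx))
  expect_equal(clean$intercept, 0, tolerance = 1e-10)
  expect_gt(clean$pval, 0.99)
  set.seed(9)
  noisy <- egger_intercept_test(
    make_instr(bx, 0.1 + 0.4 * bx + rnorm(6, 0, 1e-4), sey = rep(1e-3, 6))
  )
  expect_equal(noisy$intercept, 0.1, tolerance = 0.01)
  expect_lt(noisy$pval, 1e-4)
})

test_that("MR-PRESSO is seed-reproducible and a no-op on outlier-free input", {
  set.seed(13)
  bx <- runif(12, 0.1, 0.4)
  by <- rnorm(12, 0.3 * bx, 0.02)
  instr <- make_instr(bx, by, sey = rep(0.02, 12))
  a <- mr_presso(instr, n_sim = 300, seed = 42)
  b <- mr_presso(instr, n_sim = 300, seed = 42)
  expect_identical(a$global_pval, b$global_pval)
  expect_identical(a$outlier_pvals, b$outlier_pvals)
  expect_equal(length(a$outliers), 0)
  expect_true(is.na(a$distortion_pval))
  expect_equal(a$corrected_estimate$beta, ivw_random_effects(instr)$beta)
  # granularity of the rank-based p-value
  expect_gte(a$global_pval, 1 / 301)
  expect_error(mr_presso(make_instr(c(.1, .2, .3), c(.1, .2, .3))), "at least 4")
  expect_error(mr_presso(instr, n_sim = 50), "at least 100")
})

test_that("MR-PRESSO flags an injected pleiotropic outlier and correction reduces bias", {
  set.seed(17)
  J <- 21
  bx <- runif(J, 0.1, 0.4)
  sey <- rep(0.02, J)
  by <- rnorm(J, 0.3 * bx, sey)
  by[7] <- by[7] + 10 * median(abs(by))
  instr <- make_instr(bx, by, sey = sey)
  res <- mr_presso(instr, n_sim = 500, seed = 3)
  expect_true(instr$snp_id[7] %in% res$outliers)
  expect_lt(res$global_pval, 0.05)
  expect_false(is.na(res$distortion_pval))
  biased <- ivw_random_effects(instr)$beta
  expect_lt(abs(res$corrected_estimate$beta - 0.3), abs(biased - 0.3))
})

test_that("Steiger direction compares instrument variance explained", {
  # strong exposure signal, null outcome signal
  set.seed(19)
  bx <- runif(10, 0.2, 0.4)
  instr <- make_instr(bx, rnorm(10, 0, 0.02), sex = rep(0.01, 10),
                      sey = rep(0.02, 10), n_exp = 10000, n_out = 10000)
  st <- steiger_direction(instr)
  expect_true(st$correct_direction)
  expect_lt(st$pval, 1e-6)
  expect_gt(st$r2_exp, st$r2_out)
  # symmetric signal: direction indeterminate, p near 1
  sym <- make_instr(bx, bx, sex = rep(0.01, 10), sey = rep(0.01, 10),
                    n_exp = 10000, n_out = 10000)
  st2 <- steiger_direction(sym)
  expect_equal(st2$pval, 1)
  # simulated causal chain: correct direction nearly always
  hits <- vapply(1:100, function(r) {
    sim <- simulate_triplet(sim_config(seed = 1000 + r))
    steiger_direction(triplet_instruments(sim)$exp_out)$correct_direction
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("sensitivity reports assemble and the exclusion rule matches its definition", {
  set.seed(23)
  bx <- runif(10, 0.1, 0.4)
  instr <- make_instr(bx, rnorm(10, 0.3 * bx, 0.02), sey = rep(0.02, 10),
                      n_exp = 20000, n_out = 50000)
  rep_ <- sensitivity_report(instr, n_sim = 200, seed = 2)
  expect_s3_class(rep_, "sensitivity_report")
  expect_equal(rep_$q_df, 9)
  expect_true(all(c(rep_$q_pval, rep_$egger_intercept_pval,
                    rep_$presso_global_pval) >= 0))
  expect_equal(flag_het_pleio(rep_),
               rep_$q_pval < 0.05 || rep_$egger_intercept_pval < 0.05 ||
                 rep_$presso_global_pval < 0.05)
  # crafted reports exercise each arm of the rule
  base <- structure(list(q_pval = 0.5, egger_intercept_pval = 0.5,
                         presso_global_pval = 0.5), class = "sensitivity_report")
  expect_false(flag_het_pleio(base))
  for (fld in c("q_pval", "egger_intercept_pval", "presso_global_pval")) {
    r <- base
    r[[fld]] <- 0.01
    expect_true(flag_het_pleio(r))
    r[[fld]] <- NA_real_
    expect_false(flag_het_pleio(r))
  }
})
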