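test_that("p-value selection uses a strict threshold", {
  df <- make_records(c("rs1", "rs2", "rs3"), "A", "G", c(0.1, 0.1, 0.1))
  df$pval <- c(1e-6, 1e-5, 1e-4)
  expect_equal(select_by_pvalue(df, 1e-5)$snp_id, "rs1")
  expect_equal(nrow(select_by_pvalue(df, 1)), 3)
  # brute-force filter oracle on simulated p-values
  set.seed(4)
  big <- make_records(sprintf("rs%d", 1:200), "A", "G", rnorm(200))
  big$pval <- runif(200)
  thr <- 0.3
  expect_equal(nrow(select_by_pvalue(big, thr)), sum(big$pval < thr))
})

test_that("F-statistic is the squared z-score", {
  expect_equal(f_statistic(0.1, 0.025), 16)
  expect_equal(f_statistic(0, 0.01), 0)
  expect_equal(f_statistic(0.05, 0.01), 25)
  expect_error(f_statistic(0.1, 0))
})

test_that("greedy clumping applies window and r2 rules", {
  ld <- ld_matrix(c("a", "b"), c(1e6, 1.01e6),
                  matrix(c(1, 0.5, 0.5, 1), 2))
  cand <- make_records(c("a", "b"), "A", "G", c(0.2, 0.1),
                       pval = c(1e-8, 1e-6), pos = c(1e6, 1.01e6))
  sel <- ld_clump(cand, ld, 500, 0.1)
  expect_equal(sel$kept, "a")
  expect_equal(sel$removed, data.frame(snp_id = "b", reason = "ld",
                                       stringsAsFactors = FALSE))
  # outside the window both survive regardless of recorded r2
  ld_far <- ld_matrix(c("a", "b"), c(1e6, 1.6e6), diag(2))
  sel2 <- ld_clump(cand, ld_far, 500, 0.1)
  expect_setequal(sel2$kept, c("a", "b"))
  expect_error(ld_clump(make_records("zz", "A", "G", 0.1), ld, 500, 0.1),
               "absent from LD matrix")
})

test_that("clumping on LD blocks matches the pairwise-constraint oracle and ignores input order", {
  cfg <- sim_config(n_snps = 27, n_snps_med = 3, ld_block_size = 5,
                    ld_r2 = 0.5, seed = 8)
  ld <- simulate_ld(cfg)
  set.seed(8)
  cand <- make_records(ld$snp_ids, "A", "G", rnorm(30),
                       pval = runif(30, 1e-10, 1e-5), pos = ld$pos)
  sel <- ld_clump(cand, ld, 500, 0.1)
  expect_true(check_clump_valid(sel, cand, ld, 500, 0.1))
  expect_equal(length(sel$kept) + nrow(sel$removed), 30)
  shuffled <- cand[sample(nrow(cand)), ]
  sel2 <- ld_clump(shuffled, ld, 500, 0.1)
  expect_setequal(sel2$kept, sel$kept)
  # independence: all off-diagonal r2 zero keeps everything
  ld0 <- simulate_ld(sim_config(n_snps = 27, n_snps_med = 3,
                                ld_block_size = 1, seed = 8))
  expect_equal(length(ld_clump(cand, ld0, 500, 0.1)$kept), 30)
})

test_that("weak-instrument and confounder filters partition with single reasons", {
  sel <- mrpath:::new_selection(
    c("a", "b", "c"),
    data.frame(snp_id = character(), reason = character(),
               stringsAsFactors = FALSE),
    c(a = 16, b = 9, c = 25)
  )
  sel2 <- filter_weak(sel, 10)
  expect_equal(sel2$kept, c("a", "c"))
  expect_equal(sel2$removed$snp_id, "b")
  expect_equal(sel2$removed$reason, "weak")
  expect_equal(filter_weak(sel, 0)$kept, sel$kept)

  expect_equal(exclude_confounder_snps(sel2, character()), sel2)
  sel3 <- exclude_confounder_snps(sel2, c("c", "zz"))
  expect_equal(sel3$kept, "a")
  expect_equal(sel3$removed$reason, c("weak", "confounder"))
  expect_equal(length(sel3$kept) + nrow(sel3$removed), 3)
  # set-difference oracle on a random blacklist
  set.seed(2)
  bl <- sample(c("a", "b", "c", "x", "y"), 3)
  got <- exclude_confounder_snps(sel, bl)
  expect_setequal(got$kept, setdiff(sel$kept, bl))
})

test_that("the combined selector applies pval, ld, weak, confounder in order", {
  cfg <- sim_config(n_snps = 8, n_snps_med = 2, ld_block_size = 2,
                    ld_r2 = 0.8, seed = 5)
  ld <- simulate_ld(cfg)
  rec <- make_records(ld$snp_ids, "A", "G",
                      beta = c(rep(0.3, 8), 0.001, 0.3),
                      se = 0.02, pos = ld$pos)
  rec$pval <- c(rep(1e-8, 8), 1e-8, 0.5)
  sel <- select_instruments(rec, ld, p_threshold = 1e-5, window_kb = 500,
                            r2_threshold = 0.1, f_min = 10,
                            blacklist = ld$snp_ids[1])
  reasons <- sel$removed$reason[match(c("rs000010", "rs000009", "rs000001"),
                                      sel$removed$snp_id)]
  expect_equal(reasons, c("pval", "weak", "confounder"))
  expect_true(all(table(sel$removed$snp_id) == 1))
  expect_equal(length(sel$kept) + nrow(sel$removed), 10)
})

test_that("LD matrices round-trip through square and long TSV formats", {
  ld <- simulate_ld(sim_config(n_snps = 4, n_snps_med = 2,
                               ld_block_size = 2, ld_r2 = 0.4, seed = 1))
  path <- tempfile(fileext = ".tsv")
  write_ld_matrix(ld, path)
  back <- read_ld_matrix(path, pos = stats::setNames(ld$pos, ld$snp_ids))
  expect_equal(back$r2, ld$r2)
  long <- data.frame(snp_a = "rs000001", snp_b = "rs000002", r2 = 0.4)
  lpath <- tempfile(fileext = ".tsv")
  utils::write.table(long, lpath, sep = "\t", quote = FALSE, row.names = FALSE)
  lmat <- read_ld_matrix(lpath, pos = c(rs000001 = 1L, rs000002 = 2L))
  expect_equal(lmat$r2["rs000001", "rs000002"], 0.4)
  expect_equal(diag(lmat$r2), c(rs000001 = 1, rs000002 = 1))
})
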