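test_that("well-formed files parse fully and invalid rows are rejected with reasons", {
  df <- make_records(c("rs1", "rs2", "rs3"), "A", "G", c(0.1, -0.2, 0.05))
  path <- write_tsv_fixture(df)
  got <- read_summary_stats(path, trait_id = "t")
  expect_equal(nrow(got$records), 3)
  expect_equal(nrow(got$rejected), 0)
  expect_equal(got$records$beta, df$beta)

  bad <- df
  bad$se[2] <- 0
  bad$pval[3] <- 0
  bad <- rbind(bad, make_records("rs4", "AT", "G", 0.1))
  bad <- rbind(bad, make_records("rs5", "C", "C", 0.1))
  got <- read_summary_stats(write_tsv_fixture(bad), trait_id = "t")
  expect_equal(got$records$snp_id, "rs1")
  expect_setequal(got$rejected$reason,
                  c("nonpositive se", "pval out of range",
                    "invalid alleles", "identical alleles"))
  expect_equal(got$rejected$reason[got$rejected$snp_id == "rs2"],
               "nonpositive se")
})

test_that("column order is irrelevant given a correct schema mapping", {
  df <- make_records(c("rs1", "rs2", "rs3"), "A", "G", c(0.1, -0.2, 0.05))
  shuffled <- df[, rev(names(df))]
  a <- read_summary_stats(write_tsv_fixture(df), trait_id = "t")
  b <- read_summary_stats(write_tsv_fixture(shuffled), trait_id = "t")
  expect_equal(a$records, b$records)
})

test_that("missing required columns are a fatal configuration error", {
  df <- make_records("rs1", "A", "G", 0.1)
  df$se <- NULL
  expect_error(read_summary_stats(write_tsv_fixture(df)), "required column")
})

test_that("comma-delimited input is accepted", {
  df <- make_records(c("rs1", "rs2"), "A", "G", c(0.1, 0.2))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  got <- read_summary_stats(path, trait_id = "t")
  expect_equal(got$records$beta, df$beta)
})

test_that("harmonization aligns, flips and drops as specified", {
  exp <- make_records(c("rs1", "rs2", "rs3"), c("A", "A", "A"),
                      c("G", "G", "T"), c(0.1, 0.2, 0.3),
                      eaf = c(0.3, 0.3, 0.5), trait_id = "exp")
  out <- make_records(c("rs1", "rs2", "rs3"), c("A", "G", "A"),
                      c("G", "A", "T"), c(0.5, 0.3, 0.1),
                      eaf = c(0.3, 0.7, 0.5), trait_id = "out")
  h <- harmonize(exp, out)
  # identical coding: untouched; swapped coding: negated; ambiguous palindrome
  expect_equal(h$snp_id, c("rs1", "rs2"))
  expect_equal(h$beta_out, c(0.5, -0.3))
  expect_equal(h$flipped, c(FALSE, TRUE))
  expect_equal(h$dropped$reason, "ambiguous palindrome")
  # record count conservation over the overlap
  expect_equal(length(h$snp_id) + nrow(h$dropped), 3)
})

test_that("strand flips are resolved before declaring mismatch", {
  exp <- make_records("rs1", "A", "G", 0.1, trait_id = "exp")
  out_strand <- make_records("rs1", "T", "C", 0.4, trait_id = "out")
  h <- harmonize(exp, out_strand)
  expect_equal(h$beta_out, 0.4)
  expect_false(h$flipped)
  out_strand_swap <- make_records("rs1", "C", "T", 0.4, eaf = 0.8,
                                  trait_id = "out")
  h2 <- harmonize(exp, out_strand_swap)
  expect_equal(h2$beta_out, -0.4)
  expect_true(h2$flipped)
  out_bad <- make_records("rs1", "A", "C", 0.4, trait_id = "out")
  h3 <- tryCatch(harmonize(exp, out_bad), error = function(e) e)
  expect_s3_class(h3, "mrpath_no_overlap")
})

test_that("palindromic SNPs outside the ambiguity window orient by frequency", {
  exp <- make_records("rs1", "A", "T", 0.2, eaf = 0.2, trait_id = "exp")
  out_same <- make_records("rs1", "A", "T", 0.3, eaf = 0.21, trait_id = "out")
  h <- harmonize(exp, out_same)
  expect_equal(h$beta_out, 0.3)
  out_flip <- make_records("rs1", "A", "T", 0.3, eaf = 0.8, trait_id = "out")
  h2 <- harmonize(exp, out_flip)
  expect_equal(h2$beta_out, -0.3)
  # missing frequency on one side: palindrome dropped
  out_na <- make_records("rs1", "A", "T", 0.3, eaf = NA, trait_id = "out")
  expect_error(harmonize(exp, out_na), class = "mrpath_no_overlap")
})

test_that("harmonization is idempotent and a double swap cancels", {
  exp <- make_records(c("rs1", "rs2"), c("A", "C"), c("G", "T"),
                      c(0.1, -0.2), eaf = 0.3, trait_id = "exp")
  out <- make_records(c("rs1", "rs2"), c("G", "T"), c("A", "C"),
                      c(0.5, 0.4), eaf = 0.7, trait_id = "out")
  h1 <- harmonize(exp, out)
  # express the harmonized outcome back as records aligned to the exposure
  out2 <- make_records(c("rs1", "rs2"), c("A", "C"), c("G", "T"),
                       h1$beta_out, eaf = h1$eaf, trait_id = "out")
  h2 <- harmonize(exp, out2)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_false(any(h2$flipped))
  # swapping alleles in both files reproduces the no-swap betas
  exp_sw <- make_records(c("rs1", "rs2"), c("G", "T"), c("A", "C"),
                         -exp$beta, eaf = 0.7, trait_id = "exp")
  h3 <- harmonize(exp_sw, out)
  expect_equal(h3$beta_out, -h1$beta_out)
  expect_equal(h3$beta_out / h3$beta_exp, h1$beta_out / h1$beta_exp)
})

test_that("zero overlap raises a distinct error", {
  exp <- make_records("rs1", "A", "G", 0.1, trait_id = "exp")
  out <- make_records("rs9", "A", "G", 0.1, trait_id = "out")
  expect_error(harmonize(exp, out), class = "mrpath_no_overlap")
})

test_that("harmonized sets round-trip to TSV with provenance columns", {
  exp <- make_records(c("rs1", "rs2"), "A", "G", c(0.1, 0.2), trait_id = "exp")
  out <- make_records(c("rs1", "rs2"), c("G", "A"), c("A", "G"),
                      c(0.5, 0.4), eaf = 0.7, trait_id = "out")
  h <- harmonize(exp, out)
  path <- tempfile(fileext = ".tsv")
  write_harmonized(h, path)
  tab <- utils::read.delim(path)
  expect_true(all(c("flipped", "dropped_reason") %in% names(tab)))
  expect_equal(tab$beta_out[tab$snp_id == "rs1"], -0.5)
})
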