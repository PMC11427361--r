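# Independent oracles and fixture builders shared across the suite.
# Each oracle implements the defining computation directly, without reusing
# the package's code path.

# Weighted least squares of by on bx through the origin, weights 1/sey^2.
wls_origin_oracle <- function(bx, by, sey) {
  unname(stats::coef(stats::lm(by ~ bx - 1, weights = 1 / sey^2)))
}

# Weighted median by explicit cumulative-weight interpolation.
cumweight_median_oracle <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]
  p <- cumsum(w[o] / sum(w)) - (w[o] / sum(w)) / 2
  stats::approx(p, theta, xout = 0.5, rule = 2)$y
}

# Mode of the weighted normal-kernel density by dense grid evaluation.
grid_kde_mode_oracle <- function(theta, w, phi = 1, n_grid = 20001) {
  w <- w / sum(w)
  m <- sum(w * theta)
  s <- sqrt(sum(w * (theta - m)^2))
  h <- phi * 1.06 * s * length(theta)^(-1 / 5)
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = n_grid)
  dens <- colSums(w * sapply(grid, function(x) stats::dnorm(x, theta, h)))
  grid[which.max(dens)]
}

# Validity check for a clumping result: kept SNPs are mutually compatible,
# and every SNP removed for LD conflicts with a kept SNP of better rank.
check_clump_valid <- function(sel, cand, ld, window_kb, r2_threshold) {
  idx <- match(c(sel$kept), ld$snp_ids)
  conflict <- function(i, j) {
    ld$chrom[i] == ld$chrom[j] &&
      abs(ld$pos[i] - ld$pos[j]) <= window_kb * 1000 &&
      ld$r2[i, j] > r2_threshold
  }
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (a < b && conflict(idx[a], idx[b])) return(FALSE)
    }
  }
  rank_of <- function(id) {
    i <- match(id, cand$snp_id)
    order(order(cand$pval, ld$chrom[match(cand$snp_id, ld$snp_ids)],
                ld$pos[match(cand$snp_id, ld$snp_ids)], cand$snp_id))[i]
  }
  removed_ld <- sel$removed$snp_id[sel$removed$reason == "ld"]
  for (id in removed_ld) {
    i <- match(id, ld$snp_ids)
    hit <- FALSE
    for (kid in sel$kept) {
      k <- match(kid, ld$snp_ids)
      if (conflict(i, k) && rank_of(kid) < rank_of(id)) hit <- TRUE
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

# Shorthand harmonized set from aligned effect vectors.
make_instr <- function(bx, by, sex = rep(0.01, length(bx)),
                       sey = rep(0.02, length(bx)), ...) {
  harmonized_set(bx, sex, by, sey, ...)
}

# Summary-stat records builder for harmonization tests.
make_records <- function(snp_id, ea, oa, beta, se = 0.02, eaf = 0.3,
                         trait_id = "t", pval = 1e-8, n = 10000,
                         chrom = "1", pos = seq_along(snp_id) * 1e6) {
  data.frame(
    snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
    effect_allele = ea, other_allele = oa,
    eaf = rep_len(eaf, length(snp_id)), beta = beta,
    se = rep_len(se, length(snp_id)), pval = rep_len(pval, length(snp_id)),
    n = rep_len(n, length(snp_id)), trait_id = trait_id,
    stringsAsFactors = FALSE
  )
}

write_tsv_fixture <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
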