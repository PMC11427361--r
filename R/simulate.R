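# Synthetic two-sample GWAS summary statistics with known ground truth.
#
# Summary statistics are generated directly (no individual-level genotypes):
# per-SNP true effects are drawn, and observed betas add independent normal
# noise with the analytic standard error 1/sqrt(2 maf (1-maf) n) per panel,
# so exposure-, mediator- and outcome-panel statistics are independent given
# the true effects (the two-sample design). Binary-outcome effects are on the
# log-odds scale with the effective-sample-size variance inflation
# 1/(v (1-v)) for case fraction v.

#' Simulation configuration for an exposure-mediator-outcome chain
#'
#' The defaults emulate the structure of the data the pipeline targets:
#' a microbiome-scale exposure GWAS (n about 18,000), a small immune-trait
#' mediator GWAS (n about 3,800), and a large case-control outcome GWAS
#' (n about 290,000, case fraction about 2 percent, effects on the log-odds
#' scale). Instrument strength is set at the upper (immune-trait-like) end of
#' the realistic range, where the IVW weak-instrument attenuation is
#' negligible; see the methods vignette.
#'
#' @param n_snps Number of exposure instruments.
#' @param n_snps_med Number of instruments acting directly on the mediator.
#' @param n_exp,n_med,n_out GWAS sample sizes for the three panels.
#' @param case_fraction Outcome case fraction (binary outcome, log-odds
#'   scale).
#' @param maf_range Minor-allele-frequency bounds, in (0, 0.5].
#' @param h2_exposure Variance of the exposure explained by its instruments.
#' @param h2_mediator Variance of the mediator explained by its own
#'   instruments.
#' @param beta1_true Exposure-to-mediator effect.
#' @param beta2_true Mediator-to-outcome effect (log-odds per mediator unit).
#' @param theta_total Total exposure-to-outcome effect; either this or
#'   `direct_effect` may be given, the other is derived from
#'   `theta_total = direct_effect + beta1_true * beta2_true`.
#' @param direct_effect Direct exposure-to-outcome effect.
#' @param pleiotropy_mode `"none"`, `"balanced"` or `"directional"` pleiotropy
#'   of the exposure instruments on the outcome.
#' @param pleiotropy_mu,pleiotropy_sd Mean (directional only) and sd of the
#'   per-SNP pleiotropic effects.
#' @param n_outliers Number of exposure instruments given a large pleiotropic
#'   effect (`outlier_scale` times the median absolute true outcome effect).
#' @param outlier_scale Outlier magnitude multiplier (default 10).
#' @param ld_block_size,ld_r2 Block structure for [simulate_ld()].
#' @param seed Mandatory seed; identical configurations and seeds give
#'   bit-identical output.
#' @return A list with class `"sim_config"`.
#' @export
sim_config <- function(n_snps = 10, n_snps_med = 3,
                       n_exp = 18340, n_med = 3757, n_out = 290000,
                       case_fraction = 0.021,
                       maf_range = c(0.1, 0.4),
                       h2_exposure = 0.4, h2_mediator = 0.8,
                       beta1_true = 0.25, beta2_true = 0.35,
                       theta_total = 0.35, direct_effect = NULL,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_mu = 0.05, pleiotropy_sd = 0.05,
                       n_outliers = 0, outlier_scale = 10,
                       ld_block_size = 1, ld_r2 = 0, seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            h2_exposure > 0, h2_exposure < 1,
            h2_mediator > 0, h2_mediator < 1,
            case_fraction > 0, case_fraction < 1,
            ld_block_size >= 1, ld_r2 >= 0, ld_r2 <= 1,
            n_outliers >= 0, n_outliers <= n_snps)
  if (is.null(direct_effect)) {
    direct_effect <- theta_total - beta1_true * beta2_true
  } else {
    theta_total <- direct_effect + beta1_true * beta2_true
  }
  structure(list(
    n_snps = n_snps, n_snps_med = n_snps_med,
    n_exp = n_exp, n_med = n_med, n_out = n_out,
    case_fraction = case_fraction, maf_range = maf_range,
    h2_exposure = h2_exposure, h2_mediator = h2_mediator,
    beta1_true = beta1_true, beta2_true = beta2_true,
    theta_total = theta_total, direct_effect = direct_effect,
    pleiotropy_mode = pleiotropy_mode,
    pleiotropy_mu = pleiotropy_mu, pleiotropy_sd = pleiotropy_sd,
    n_outliers = n_outliers, outlier_scale = outlier_scale,
    ld_block_size = ld_block_size, ld_r2 = ld_r2, seed = seed
  ), class = "sim_config")
}

# Scale raw standard-normal draws so the implied variance explained equals h2.
scale_to_h2 <- function(raw, maf, h2) {
  v <- 2 * maf * (1 - maf)
  raw * sqrt(h2 / sum(v * raw^2))
}

sumstat_frame <- function(snp_id, chrom, pos, eaf, beta, se, n, trait_id) {
  data.frame(
    snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = "A", other_allele = "G",
    eaf = eaf, beta = beta, se = se,
    # floor against underflow for very strong associations: p must stay in (0, 1]
    pval = pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin),
    n = n, trait_id = trait_id,
    stringsAsFactors = FALSE
  )
}

#' Simulate an exposure-mediator-outcome summary-statistics triplet
#'
#' Draws per-SNP true exposure effects scaled to `h2_exposure`; the mediator
#' inherits `beta1_true` times those effects and has `n_snps_med` instruments
#' of its own scaled to `h2_mediator`; the outcome receives
#' `theta_total = direct_effect + beta1_true * beta2_true` times the exposure
#' effects, `beta2_true` times the mediator-specific effects, and any
#' configured pleiotropy or outlier effects. Observed statistics add
#' independent panel noise at the analytic standard errors.
#'
#' @param config A `"sim_config"`.
#' @param dir Optional directory: when given, the three summary-statistic
#'   TSVs and a `truth.json` sidecar are written there.
#' @return List with `exposure`, `mediator`, `outcome` (summary-stat data
#'   frames in the generic dialect), `truth` (true effects and parameters)
#'   and `config`.
#' @export
simulate_triplet <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  Jx <- config$n_snps
  Jm <- config$n_snps_med
  J <- Jx + Jm
  maf <- stats::runif(J, config$maf_range[1], config$maf_range[2])
  snp_id <- sprintf("rs%06d", seq_len(J))
  block <- (seq_len(J) - 1) %/% config$ld_block_size
  within <- (seq_len(J) - 1) %% config$ld_block_size
  pos <- as.integer(block * 1e6 + within * 1e4 + 1)
  chrom <- "1"

  idx_x <- seq_len(Jx)
  idx_m <- Jx + seq_len(Jm)
  gamma <- numeric(J)
  delta <- numeric(J)
  gamma[idx_x] <- scale_to_h2(stats::rnorm(Jx), maf[idx_x], config$h2_exposure)
  delta[idx_m] <- scale_to_h2(stats::rnorm(Jm), maf[idx_m], config$h2_mediator)

  alpha <- numeric(J)
  if (config$pleiotropy_mode == "balanced") {
    alpha[idx_x] <- stats::rnorm(Jx, 0, config$pleiotropy_sd)
  } else if (config$pleiotropy_mode == "directional") {
    alpha[idx_x] <- stats::rnorm(Jx, config$pleiotropy_mu, config$pleiotropy_sd)
  }

  true_exp <- gamma
  true_med <- config$beta1_true * gamma + delta
  true_out <- config$theta_total * gamma + config$beta2_true * delta + alpha

  outlier_snps <- character()
  if (config$n_outliers > 0) {
    pick <- sample(idx_x, config$n_outliers)
    bump <- config$outlier_scale * stats::median(abs(true_out[idx_x]))
    true_out[pick] <- true_out[pick] + bump
    outlier_snps <- snp_id[pick]
  }

  v <- 2 * maf * (1 - maf)
  se_exp <- 1 / sqrt(v * config$n_exp)
  se_med <- 1 / sqrt(v * config$n_med)
  phi <- config$case_fraction * (1 - config$case_fraction)
  se_out <- 1 / sqrt(v * config$n_out * phi)

  exposure <- sumstat_frame(snp_id, chrom, pos, maf,
                            true_exp + stats::rnorm(J, 0, se_exp), se_exp,
                            config$n_exp, "exposure")
  mediator <- sumstat_frame(snp_id, chrom, pos, maf,
                            true_med + stats::rnorm(J, 0, se_med), se_med,
                            config$n_med, "mediator")
  outcome <- sumstat_frame(snp_id, chrom, pos, maf,
                           true_out + stats::rnorm(J, 0, se_out), se_out,
                           config$n_out, "outcome")

  truth <- list(
    gamma = stats::setNames(gamma, snp_id),
    delta = stats::setNames(delta, snp_id),
    alpha = stats::setNames(alpha, snp_id),
    true_out = stats::setNames(true_out, snp_id),
    beta1 = config$beta1_true, beta2 = config$beta2_true,
    beta3 = config$theta_total, direct_effect = config$direct_effect,
    proportion_pct = 100 * config$beta1_true * config$beta2_true /
      config$theta_total,
    exposure_snps = snp_id[idx_x], mediator_snps = snp_id[idx_m],
    outlier_snps = outlier_snps
  )

  out <- list(exposure = exposure, mediator = mediator, outcome = outcome,
              truth = truth, config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_summary_stats(exposure, file.path(dir, "exposure.tsv"))
    write_summary_stats(mediator, file.path(dir, "mediator.tsv"))
    write_summary_stats(outcome, file.path(dir, "outcome.tsv"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Simulate a block-diagonal LD matrix
#'
#' Squared correlations equal `ld_r2` within consecutive blocks of
#' `ld_block_size` SNPs and zero across blocks. Positions are spaced 10 kb
#' apart within a block and 1 Mb between blocks, so blocks fall inside the
#' default 500 kb clumping window and distinct blocks fall outside it.
#'
#' @param config A `"sim_config"` (uses `n_snps`, `n_snps_med`,
#'   `ld_block_size`, `ld_r2`).
#' @return An `"ld_matrix"` covering the SNPs of [simulate_triplet()] under
#'   the same config.
#' @export
simulate_ld <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  J <- config$n_snps + config$n_snps_med
  snp_id <- sprintf("rs%06d", seq_len(J))
  block <- (seq_len(J) - 1) %/% config$ld_block_size
  within <- (seq_len(J) - 1) %% config$ld_block_size
  pos <- as.integer(block * 1e6 + within * 1e4 + 1)
  r2 <- outer(block, block, "==") * config$ld_r2
  diag(r2) <- 1
  ld_matrix(snp_id, pos, r2)
}

#' Simulate a multi-candidate panel for model averaging
#'
#' Builds `d` candidate exposures measured on a shared instrument panel:
#' each candidate has `n_private` instruments of its own plus `n_shared`
#' instruments loading on every candidate (inducing correlation between
#' candidate effect vectors). The outcome is generated from the true causal
#' subset only.
#'
#' @param d Number of candidates (at least 2).
#' @param true_causal Integer indices of the causal candidates (possibly
#'   empty).
#' @param theta Causal effect(s) of the true candidates (recycled).
#' @param n_private,n_shared Instruments per candidate and shared.
#' @param effect_private,effect_shared Mean absolute per-SNP effects.
#' @param se_x,se_y Observation noise for exposure and outcome panels.
#' @param seed Seed.
#' @return List with `input` (a `"bma_input"`) and `truth` (causal set and
#'   effects).
#' @export
simulate_multicandidate <- function(d, true_causal = integer(), theta = 0.3,
                                    n_private = 8, n_shared = 6,
                                    effect_private = 0.2, effect_shared = 0.1,
                                    se_x = 0.02, se_y = 0.02, seed = 1) {
  stopifnot(d >= 2, all(true_causal %in% seq_len(d)))
  set.seed(seed)
  J <- d * n_private + n_shared
  X <- matrix(0, J, d)
  for (k in seq_len(d)) {
    rows <- (k - 1) * n_private + seq_len(n_private)
    X[rows, k] <- stats::rnorm(n_private, effect_private, effect_private / 4) *
      sample(c(-1, 1), n_private, replace = TRUE)
  }
  if (n_shared > 0) {
    rows <- d * n_private + seq_len(n_shared)
    base <- stats::rnorm(n_shared, effect_shared, effect_shared / 4) *
      sample(c(-1, 1), n_shared, replace = TRUE)
    for (k in seq_len(d)) {
      X[rows, k] <- base + stats::rnorm(n_shared, 0, effect_shared / 4)
    }
  }
  theta_vec <- numeric(d)
  theta_vec[true_causal] <- rep_len(theta, length(true_causal))
  beta_y_true <- drop(X %*% theta_vec)
  input <- bma_input(
    beta_x = X + stats::rnorm(J * d, 0, se_x),
    se_x = matrix(se_x, J, d),
    beta_y = beta_y_true + stats::rnorm(J, 0, se_y),
    se_y = rep(se_y, J),
    candidate_ids = paste0("candidate_", seq_len(d))
  )
  list(input = input,
       truth = list(true_causal = true_causal, theta = theta_vec))
}

#' Convert a simulated triplet into harmonized instrument sets
#'
#' Convenience wrapper assembling the three univariate analyses of the
#' two-step design from one simulated chain: exposure to outcome (on the
#' exposure's instruments), exposure to mediator (same instruments), and
#' mediator to outcome (on the mediator's own instruments).
#'
#' @param sim Output of [simulate_triplet()].
#' @return List of `"harmonized_set"` objects `exp_out`, `exp_med`,
#'   `med_out`.
#' @export
triplet_instruments <- function(sim) {
  xs <- sim$truth$exposure_snps
  ms <- sim$truth$mediator_snps
  pick <- function(df, ids) df[match(ids, df$snp_id), ]
  make <- function(a, b, ids) {
    ar <- pick(a, ids)
    br <- pick(b, ids)
    harmonized_set(ar$beta, ar$se, br$beta, br$se, snp_id = ids,
                   exposure_id = ar$trait_id[1], outcome_id = br$trait_id[1],
                   eaf = ar$eaf, n_exp = ar$n[1], n_out = br$n[1])
  }
  list(exp_out = make(sim$exposure, sim$outcome, xs),
       exp_med = make(sim$exposure, sim$mediator, xs),
       med_out = make(sim$mediator, sim$outcome, ms))
}
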