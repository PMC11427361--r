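# Reading, validating and harmonizing GWAS summary statistics.

VALID_ALLELES <- c("A", "C", "G", "T")

#' Column-name presets for common summary-statistic dialects
#'
#' Returns a named list mapping the roles required by
#' [read_summary_stats()] (`snp`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`) to the column names used
#' by a given file dialect.
#'
#' @param name One of `"generic"`, `"finngen-like"`, `"mibiogen-like"`.
#' @return Named list of column names, usable as the `schema` argument of
#'   [read_summary_stats()].
#' @export
#' @examples
#' schema_preset("generic")
schema_preset <- function(name = c("generic", "finngen-like", "mibiogen-like")) {
  name <- match.arg(name)
  switch(name,
    "generic" = list(
      snp = "snp_id", chrom = "chrom", pos = "pos",
      effect_allele = "effect_allele", other_allele = "other_allele",
      eaf = "eaf", beta = "beta", se = "se", pval = "pval", n = "n"
    ),
    "finngen-like" = list(
      snp = "rsids", chrom = "chrom", pos = "pos",
      effect_allele = "alt", other_allele = "ref",
      eaf = "af_alt", beta = "beta", se = "sebeta", pval = "pval", n = "n"
    ),
    "mibiogen-like" = list(
      snp = "rsID", chrom = "chr", pos = "bp",
      effect_allele = "eff.allele", other_allele = "ref.allele",
      eaf = "eaf", beta = "beta", se = "SE", pval = "P.weightedSumZ", n = "N"
    )
  )
}

#' Read GWAS summary statistics from a delimited file
#'
#' Parses a headered, tab- or comma-delimited summary-statistics file into a
#' validated per-SNP association table. Rows that violate the record
#' invariants (non-ACGT or identical alleles, non-positive standard error,
#' p-value outside (0, 1], allele frequency outside \[0, 1\], unparseable
#' numerics) are collected with a reason rather than silently dropped.
#' Indels and multi-allelic sites are rejected at parse time: the downstream
#' analysis is SNP-only.
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param schema Named list mapping roles to column names, e.g. from
#'   [schema_preset()]. The `eaf`, `chrom`, `pos` and `n` roles are optional;
#'   all others are required.
#' @param trait_id Identifier attached to every record (defaults to the file
#'   name without extension).
#' @return A list with class `"gwas_sumstats"`:
#'   \describe{
#'     \item{records}{data frame with columns `snp_id`, `chrom`, `pos`,
#'       `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`,
#'       `trait_id`.}
#'     \item{rejected}{data frame with columns `snp_id`, `reason`.}
#'   }
#' @export
read_summary_stats <- function(path, schema = schema_preset("generic"),
                               trait_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  required <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
  optional <- c("chrom", "pos", "eaf", "n")
  for (role in required) {
    col <- schema[[role]]
    if (is.null(col) || !col %in% names(raw)) {
      stop("required column for role '", role, "' (", col %||% "<unset>",
           ") missing from ", path, call. = FALSE)
    }
  }
  get_col <- function(role) {
    col <- schema[[role]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  rec <- data.frame(
    snp_id = get_col("snp"),
    chrom = get_col("chrom"),
    pos = suppressWarnings(as.integer(get_col("pos"))),
    effect_allele = toupper(trimws(get_col("effect_allele"))),
    other_allele = toupper(trimws(get_col("other_allele"))),
    eaf = num(get_col("eaf")),
    beta = num(get_col("beta")),
    se = num(get_col("se")),
    pval = num(get_col("pval")),
    n = suppressWarnings(as.integer(get_col("n"))),
    trait_id = trait_id,
    stringsAsFactors = FALSE
  )
  validate_sumstats(rec)
}

#' Validate a summary-statistics data frame
#'
#' Applies the per-record invariants and splits rows into accepted records
#' and rejections with reasons. Used internally by [read_summary_stats()] and
#' exported so in-memory tables (e.g. simulated ones) can be checked the same
#' way.
#'
#' @param rec Data frame with the columns produced by [read_summary_stats()].
#' @return A `"gwas_sumstats"` list with `records` and `rejected` entries.
#' @export
validate_sumstats <- function(rec) {
  reason <- rep(NA_character_, nrow(rec))
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why
  had_beta <- !is.na(rec$beta); had_se <- !is.na(rec$se); had_p <- !is.na(rec$pval)
  flag(!had_beta | !had_se | !had_p, "unparseable numeric")
  flag(!(rec$effect_allele %in% VALID_ALLELES) |
         !(rec$other_allele %in% VALID_ALLELES), "invalid alleles")
  flag(rec$effect_allele == rec$other_allele, "identical alleles")
  flag(had_se & rec$se <= 0, "nonpositive se")
  flag(had_p & (rec$pval <= 0 | rec$pval > 1), "pval out of range")
  flag(!is.na(rec$eaf) & (rec$eaf < 0 | rec$eaf > 1), "eaf out of range")
  keep <- is.na(reason)
  out <- list(
    records = rec[keep, , drop = FALSE],
    rejected = data.frame(snp_id = rec$snp_id[!keep],
                          reason = reason[!keep],
                          stringsAsFactors = FALSE)
  )
  rownames(out$records) <- NULL
  class(out) <- "gwas_sumstats"
  out
}

#' @export
print.gwas_sumstats <- function(x, ...) {
  cat("GWAS summary statistics:", nrow(x$records), "records,",
      nrow(x$rejected), "rejected rows\n")
  invisible(x)
}

complement_allele <- function(a) c(A = "T", T = "A", C = "G", G = "C")[a]

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome associations to the exposure's effect allele for the SNPs
#' present in both traits. If the outcome file codes the alleles the other
#' way round, the outcome beta is negated and the allele frequency
#' complemented; strand flips (allele complements) are resolved before a
#' mismatch is declared. Palindromic SNPs (A/T or C/G) cannot be
#' strand-resolved, so they are dropped as ambiguous whenever the effect
#' allele frequency is missing on either side or lies within
#' `palindrome_eaf_window` of 0.5 on either side; unambiguous palindromes are
#' oriented by frequency concordance.
#'
#' @param exposure,outcome `"gwas_sumstats"` objects (or their `records` data
#'   frames).
#' @param palindrome_eaf_window Half-width of the ambiguity window around an
#'   allele frequency of 0.5 (default 0.08, i.e. drop when
#'   min(eaf, 1 - eaf) > 0.42).
#' @return A list with class `"harmonized_set"`: `exposure_id`, `outcome_id`,
#'   `snp_id`, `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf`, `n_exp`,
#'   `n_out`, `flipped` (logical), and `dropped` (data frame of snp_id,
#'   reason).
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  ex <- if (inherits(exposure, "gwas_sumstats")) exposure$records else exposure
  ou <- if (inherits(outcome, "gwas_sumstats")) outcome$records else outcome
  if (nrow(ex) == 0L || nrow(ou) == 0L) stop("empty summary-statistics input")
  ou <- ou[match(ex$snp_id, ou$snp_id), , drop = FALSE]
  overlap <- !is.na(ou$snp_id)
  if (!any(overlap)) {
    stop(structure(class = c("mrpath_no_overlap", "error", "condition"),
                   list(message = "no overlapping SNPs between exposure and outcome",
                        call = sys.call())))
  }
  ex <- ex[overlap, , drop = FALSE]
  ou <- ou[overlap, , drop = FALSE]
  J <- nrow(ex)
  flipped <- logical(J)
  reason <- rep(NA_character_, J)
  beta_out <- ou$beta
  eaf_out <- ou$eaf

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  same <- ou$effect_allele == ex$effect_allele & ou$other_allele == ex$other_allele
  swap <- ou$effect_allele == ex$other_allele & ou$other_allele == ex$effect_allele
  ceff <- complement_allele(ou$effect_allele)
  coth <- complement_allele(ou$other_allele)
  strand <- !pal & ceff == ex$effect_allele & coth == ex$other_allele
  strand_swap <- !pal & ceff == ex$other_allele & coth == ex$effect_allele

  do_flip <- (swap | strand_swap) & !pal
  beta_out[do_flip] <- -beta_out[do_flip]
  eaf_out[do_flip] <- 1 - eaf_out[do_flip]
  flipped[do_flip] <- TRUE
  reason[!(same | swap | strand | strand_swap)] <- "allele mismatch"

  if (any(pal & is.na(reason))) {
    w <- palindrome_eaf_window
    amb <- pal & is.na(reason) &
      (is.na(ex$eaf) | is.na(eaf_out) |
         (ex$eaf >= 0.5 - w & ex$eaf <= 0.5 + w) |
         (eaf_out >= 0.5 - w & eaf_out <= 0.5 + w))
    reason[amb] <- "ambiguous palindrome"
    # Unambiguous palindromes: orient by frequency concordance. For a swapped
    # coding the reported outcome eaf refers to the exposure's other allele,
    # so discordant frequency sides imply a flip.
    res <- pal & is.na(reason)
    if (any(res)) {
      discord <- res & ((ex$eaf > 0.5) != (eaf_out > 0.5))
      beta_out[discord] <- -beta_out[discord]
      eaf_out[discord] <- 1 - eaf_out[discord]
      flipped[discord] <- TRUE
    }
  }

  keep <- is.na(reason)
  if (!any(keep)) {
    stop(structure(class = c("mrpath_no_overlap", "error", "condition"),
                   list(message = "all overlapping SNPs dropped during harmonization",
                        call = sys.call())))
  }
  structure(list(
    exposure_id = ex$trait_id[1] %||% "exposure",
    outcome_id = ou$trait_id[1] %||% "outcome",
    snp_id = ex$snp_id[keep],
    beta_exp = ex$beta[keep],
    se_exp = ex$se[keep],
    beta_out = beta_out[keep],
    se_out = ou$se[keep],
    eaf = ex$eaf[keep],
    n_exp = stats::median(ex$n[keep], na.rm = TRUE),
    n_out = stats::median(ou$n[keep], na.rm = TRUE),
    flipped = flipped[keep],
    dropped = data.frame(snp_id = ex$snp_id[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  ), class = "harmonized_set")
}

#' Construct a harmonized instrument set from aligned vectors
#'
#' Convenience constructor for analyses where per-SNP exposure and outcome
#' effects are already on a common effect allele (e.g. simulated data).
#'
#' @param beta_exp,se_exp,beta_out,se_out Numeric vectors of equal length.
#' @param snp_id Optional SNP identifiers.
#' @param exposure_id,outcome_id Trait labels.
#' @param eaf Optional effect-allele frequencies.
#' @param n_exp,n_out Optional sample sizes.
#' @return A `"harmonized_set"` object.
#' @export
harmonized_set <- function(beta_exp, se_exp, beta_out, se_out,
                           snp_id = paste0("rs", seq_along(beta_exp)),
                           exposure_id = "exposure", outcome_id = "outcome",
                           eaf = rep(NA_real_, length(beta_exp)),
                           n_exp = NA_integer_, n_out = NA_integer_) {
  J <- length(beta_exp)
  stopifnot(length(se_exp) == J, length(beta_out) == J, length(se_out) == J,
            J >= 1, all(se_exp > 0), all(se_out > 0))
  structure(list(
    exposure_id = exposure_id, outcome_id = outcome_id, snp_id = snp_id,
    beta_exp = beta_exp, se_exp = se_exp, beta_out = beta_out,
    se_out = se_out, eaf = eaf, n_exp = n_exp, n_out = n_out,
    flipped = logical(J),
    dropped = data.frame(snp_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  ), class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized instrument set:", x$exposure_id, "->", x$outcome_id, "\n")
  cat(" ", length(x$snp_id), "aligned SNPs (", sum(x$flipped), "flipped,",
      nrow(x$dropped), "dropped )\n")
  invisible(x)
}

#' Number of instruments in a harmonized set
#' @param x A `"harmonized_set"` object.
#' @return Integer count of aligned SNPs.
#' @export
n_snp <- function(x) length(x$snp_id)

#' Write a harmonized instrument set to TSV
#'
#' Emits one row per aligned SNP with provenance columns (`flipped`), followed
#' by the dropped SNPs with their `dropped_reason`.
#'
#' @param x A `"harmonized_set"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(x, path) {
  kept <- data.frame(
    snp_id = x$snp_id, beta_exp = x$beta_exp, se_exp = x$se_exp,
    beta_out = x$beta_out, se_out = x$se_out, eaf = x$eaf,
    flipped = x$flipped, dropped_reason = NA_character_,
    stringsAsFactors = FALSE
  )
  if (nrow(x$dropped)) {
    drop <- data.frame(
      snp_id = x$dropped$snp_id, beta_exp = NA_real_, se_exp = NA_real_,
      beta_out = NA_real_, se_out = NA_real_, eaf = NA_real_,
      flipped = NA, dropped_reason = x$dropped$reason, stringsAsFactors = FALSE
    )
    kept <- rbind(kept, drop)
  }
  utils::write.table(kept, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write summary statistics in the generic TSV dialect
#'
#' @param x A `"gwas_sumstats"` object or a records data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  rec <- if (inherits(x, "gwas_sumstats")) x$records else x
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a
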