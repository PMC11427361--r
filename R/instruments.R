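# Instrument selection: p-value thresholding, LD clumping, strength and
# confounder filters.

#' Construct an LD matrix object
#'
#' @param snp_ids Character vector of SNP identifiers.
#' @param pos Integer vector of base-pair positions (1-based).
#' @param r2 Square symmetric matrix of squared correlations with unit
#'   diagonal, rows/columns in `snp_ids` order.
#' @param chrom Chromosome labels (recycled if length 1).
#' @return A list with class `"ld_matrix"`.
#' @export
ld_matrix <- function(snp_ids, pos, r2, chrom = "1") {
  r2 <- as.matrix(r2)
  stopifnot(length(snp_ids) == length(pos),
            nrow(r2) == length(snp_ids), ncol(r2) == length(snp_ids))
  if (max(abs(r2 - t(r2))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("LD matrix must have unit diagonal")
  if (min(r2) < -1e-8 || max(r2) > 1 + 1e-8) stop("r2 values must lie in [0, 1]")
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, pos = as.integer(pos),
                 chrom = rep_len(as.character(chrom), length(snp_ids)),
                 r2 = r2),
            class = "ld_matrix")
}

#' Read an LD matrix from TSV
#'
#' Accepts either a square matrix (header row = SNP ids, first column = SNP
#' ids) or long-format triples with columns `snp_a`, `snp_b`, `r2`. Positions
#' must be supplied separately for the long format.
#'
#' @param path File path.
#' @param pos Named integer vector of positions (required for long format; for
#'   the square format it may be omitted if a `pos` column is absent, in which
#'   case positions default to the SNP order spaced 1 Mb apart).
#' @param chrom Chromosome labels, as in [ld_matrix()].
#' @return An `"ld_matrix"` object.
#' @export
read_ld_matrix <- function(path, pos = NULL, chrom = "1") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (all(c("snp_a", "snp_b", "r2") %in% names(tab))) {
    ids <- sort(unique(c(tab$snp_a, tab$snp_b)))
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    m[cbind(tab$snp_a, tab$snp_b)] <- tab$r2
    m[cbind(tab$snp_b, tab$snp_a)] <- tab$r2
  } else {
    ids <- names(tab)[-1]
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    m <- m[ids, ids, drop = FALSE]
  }
  if (is.null(pos)) pos <- stats::setNames(seq_along(ids) * 1e6L, ids)
  ld_matrix(ids, pos[ids], m, chrom = chrom)
}

#' Write an LD matrix to square TSV
#' @param ld An `"ld_matrix"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  out <- data.frame(snp_id = ld$snp_ids, ld$r2, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter records by association p-value
#'
#' Keeps exactly the records with `pval` strictly below the threshold.
#'
#' @param records A `"gwas_sumstats"` object or records data frame.
#' @param p_threshold Threshold in (0, 1); default `1e-5`, the conventional
#'   genome-wide-suggestive cut used for microbiome and immune-trait
#'   instruments.
#' @return Records data frame restricted to sub-threshold SNPs.
#' @export
select_by_pvalue <- function(records, p_threshold = 1e-5) {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  rec <- if (inherits(records, "gwas_sumstats")) records$records else records
  out <- rec[rec$pval < p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-SNP instrument-strength F-statistic
#'
#' The squared z-score `(beta/se)^2`, the per-SNP approximation of the
#' first-stage F-statistic. Values above 10 conventionally indicate a strong
#' instrument.
#'
#' @param beta,se Numeric vectors (se strictly positive).
#' @return Numeric vector of F-statistics.
#' @export
#' @examples
#' f_statistic(0.1, 0.025) # 16
f_statistic <- function(beta, se) {
  stopifnot(all(se > 0))
  (beta / se)^2
}

new_selection <- function(kept, removed, f_stats) {
  structure(list(kept = kept, removed = removed, f_stats = f_stats),
            class = "instrument_selection")
}

#' @export
print.instrument_selection <- function(x, ...) {
  cat("Instrument selection:", length(x$kept), "kept,",
      nrow(x$removed), "removed\n")
  if (nrow(x$removed)) print(table(x$removed$reason))
  invisible(x)
}

#' Greedy LD clumping of candidate instruments
#'
#' Candidates are sorted by ascending p-value (ties broken by chromosome,
#' position, then SNP id, so the result is independent of input order). The
#' best remaining SNP is kept and every other candidate on the same
#' chromosome within `window_kb` kilobases having squared correlation above
#' `r2_threshold` with it is removed, until no candidates remain.
#'
#' @param candidates Records data frame (needs `snp_id`, `pval`; `chrom`/`pos`
#'   are taken from `ld` when absent).
#' @param ld An `"ld_matrix"` covering every candidate.
#' @param window_kb Clumping window in kb (default 500).
#' @param r2_threshold Squared-correlation threshold (default 0.1).
#' @return An `"instrument_selection"` with removal reason `"ld"` and
#'   `f_stats` computed from the candidate betas.
#' @export
ld_clump <- function(candidates, ld, window_kb = 500, r2_threshold = 0.1) {
  stopifnot(window_kb > 0)
  cand <- if (inherits(candidates, "gwas_sumstats")) candidates$records else candidates
  miss <- setdiff(cand$snp_id, ld$snp_ids)
  if (length(miss)) {
    stop("candidates absent from LD matrix: ", paste(miss, collapse = ", "))
  }
  idx <- match(cand$snp_id, ld$snp_ids)
  pos <- ld$pos[idx]
  chrom <- ld$chrom[idx]
  ord <- order(cand$pval, chrom, pos, cand$snp_id)
  kept <- character()
  removed_id <- character()
  active <- ord
  while (length(active)) {
    best <- active[1]
    kept <- c(kept, cand$snp_id[best])
    active <- active[-1]
    if (length(active)) {
      near <- chrom[active] == chrom[best] &
        abs(pos[active] - pos[best]) <= window_kb * 1000
      high <- ld$r2[cbind(idx[active], idx[best])] > r2_threshold
      prune <- near & high
      removed_id <- c(removed_id, cand$snp_id[active[prune]])
      active <- active[!prune]
    }
  }
  f <- stats::setNames(f_statistic(cand$beta, cand$se), cand$snp_id)
  new_selection(
    kept,
    data.frame(snp_id = removed_id,
               reason = rep("ld", length(removed_id)),
               stringsAsFactors = FALSE),
    f
  )
}

#' Remove weak instruments from a selection
#'
#' SNPs whose F-statistic does not exceed `f_min` are moved to the removed
#' set with reason `"weak"`.
#'
#' @param selection An `"instrument_selection"`.
#' @param f_min Minimum F-statistic (strict; default 10).
#' @return Updated `"instrument_selection"`.
#' @export
filter_weak <- function(selection, f_min = 10) {
  f <- selection$f_stats[selection$kept]
  weak <- selection$kept[f <= f_min]
  selection$kept <- setdiff(selection$kept, weak)
  if (length(weak)) {
    selection$removed <- rbind(
      selection$removed,
      data.frame(snp_id = weak, reason = "weak", stringsAsFactors = FALSE)
    )
  }
  selection
}

#' Exclude confounder-associated SNPs
#'
#' Moves blacklisted SNPs (e.g. variants strongly associated with smoking or
#' alcohol consumption) to the removed set with reason `"confounder"`.
#'
#' @param selection An `"instrument_selection"`.
#' @param blacklist Character vector of SNP ids (may be empty).
#' @return Updated `"instrument_selection"`.
#' @export
exclude_confounder_snps <- function(selection, blacklist = character()) {
  hit <- intersect(selection$kept, blacklist)
  selection$kept <- setdiff(selection$kept, hit)
  if (length(hit)) {
    selection$removed <- rbind(
      selection$removed,
      data.frame(snp_id = hit, reason = "confounder", stringsAsFactors = FALSE)
    )
  }
  selection
}

#' Full instrument-selection pipeline for one exposure
#'
#' Applies, in order: the p-value threshold (removed reason `"pval"`), greedy
#' LD clumping (`"ld"`), the weak-instrument filter (`"weak"`), and the
#' confounder blacklist (`"confounder"`).
#'
#' @inheritParams ld_clump
#' @inheritParams select_by_pvalue
#' @inheritParams filter_weak
#' @inheritParams exclude_confounder_snps
#' @param records A `"gwas_sumstats"` object or records data frame.
#' @return An `"instrument_selection"` partitioning the input SNPs.
#' @export
select_instruments <- function(records, ld, p_threshold = 1e-5,
                               window_kb = 500, r2_threshold = 0.1,
                               f_min = 10, blacklist = character()) {
  rec <- if (inherits(records, "gwas_sumstats")) records$records else records
  pass <- select_by_pvalue(rec, p_threshold)
  sel <- if (nrow(pass)) {
    ld_clump(pass, ld, window_kb, r2_threshold)
  } else {
    new_selection(character(),
                  data.frame(snp_id = character(), reason = character(),
                             stringsAsFactors = FALSE),
                  stats::setNames(numeric(), character()))
  }
  failed <- setdiff(rec$snp_id, pass$snp_id)
  if (length(failed)) {
    sel$removed <- rbind(
      data.frame(snp_id = failed, reason = rep("pval", length(failed)),
                 stringsAsFactors = FALSE),
      sel$removed
    )
  }
  sel$f_stats <- stats::setNames(f_statistic(rec$beta, rec$se), rec$snp_id)
  sel <- filter_weak(sel, f_min)
  exclude_confounder_snps(sel, blacklist)
}

#' Read a one-SNP-per-line blacklist file
#' @param path Text file with one SNP id per line (blank lines and `#`
#'   comments ignored).
#' @return Character vector of SNP ids.
#' @export
read_blacklist <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
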