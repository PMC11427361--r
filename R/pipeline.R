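# Study orchestration: univariate screens, sensitivity gating, FDR,
# model-averaging prioritization, mediation screening, report emission.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (a thin, name-stable wrapper over
#' `stats::p.adjust(method = "BH")`): adjusted values are monotone in the
#' raw p-values, elementwise at least as large, and capped at 1.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Vector of adjusted p-values.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
bh_fdr <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Study configuration
#'
#' Bundles the trait tables and thresholds for a full screen. Traits may be
#' given as `"gwas_sumstats"` objects, records data frames, or file paths
#' (read with [read_summary_stats()] and the `schema`).
#'
#' @param exposures Named list of exposure traits.
#' @param outcomes Named list of outcome traits.
#' @param mediators Named list of mediator traits (optional).
#' @param ld An `"ld_matrix"` covering every instrument candidate, or a file
#'   path for [read_ld_matrix()].
#' @param categories Optional named character vector mapping exposure ids to
#'   panel categories for the grouped model-averaging stage.
#' @param schema Column schema for file inputs.
#' @param p_instr Instrument p-value threshold (default 1e-5).
#' @param clump_kb,clump_r2 LD-clumping window and threshold (500 kb, 0.1).
#' @param f_min Instrument-strength threshold (default 10).
#' @param alpha Significance level for screens and diagnostics (0.05).
#' @param fdr_q FDR level used when reporting adjusted significance (0.05).
#' @param mip_threshold Importance flag threshold on MIP (0.1).
#' @param prior_prob,prior_variance,n_iter Model-averaging settings
#'   (0.1, 0.5, 10000).
#' @param n_sim Simulation budget for the pleiotropy outlier test (1000).
#' @param blacklist Confounder SNP ids to exclude.
#' @param seed Seed governing every stochastic component.
#' @return A list with class `"study_config"`.
#' @export
study_config <- function(exposures, outcomes, mediators = list(), ld = NULL,
                         categories = NULL, schema = schema_preset("generic"),
                         p_instr = 1e-5, clump_kb = 500, clump_r2 = 0.1,
                         f_min = 10, alpha = 0.05, fdr_q = 0.05,
                         mip_threshold = 0.1, prior_prob = 0.1,
                         prior_variance = 0.5, n_iter = 10000, n_sim = 1000,
                         blacklist = character(), seed = 1) {
  stopifnot(length(exposures) >= 1, length(outcomes) >= 1,
            !is.null(names(exposures)), !is.null(names(outcomes)))
  if (anyDuplicated(c(names(exposures), names(outcomes), names(mediators)))) {
    stop("trait ids must be unique across exposures, outcomes and mediators")
  }
  structure(list(
    exposures = exposures, outcomes = outcomes, mediators = mediators,
    ld = ld, categories = categories, schema = schema,
    p_instr = p_instr, clump_kb = clump_kb, clump_r2 = clump_r2,
    f_min = f_min, alpha = alpha, fdr_q = fdr_q,
    mip_threshold = mip_threshold, prior_prob = prior_prob,
    prior_variance = prior_variance, n_iter = n_iter, n_sim = n_sim,
    blacklist = blacklist, seed = seed
  ), class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Expects top-level keys `exposures`, `outcomes`, optionally `mediators`
#' (each a named map of id to file path), `ld` (file path), `schema` (preset
#' name), `categories` (map id to category) and any threshold fields of
#' [study_config()].
#'
#' @param path YAML file path.
#' @return A `"study_config"`.
#' @export
read_study_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configurations")
  }
  y <- yaml::yaml.load_file(path)
  args <- list(
    exposures = as.list(y$exposures), outcomes = as.list(y$outcomes),
    mediators = as.list(y$mediators %||% list()),
    ld = y$ld, categories = unlist(y$categories),
    schema = schema_preset(y$schema %||% "generic")
  )
  for (k in c("p_instr", "clump_kb", "clump_r2", "f_min", "alpha", "fdr_q",
              "mip_threshold", "prior_prob", "prior_variance", "n_iter",
              "n_sim", "seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$blacklist)) args$blacklist <- read_blacklist(y$blacklist)
  do.call(study_config, args)
}

rbind_rows <- function(rows) {
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

load_trait <- function(x, id, schema) {
  if (inherits(x, "gwas_sumstats")) return(x)
  if (is.character(x) && length(x) == 1) {
    return(read_summary_stats(x, schema = schema, trait_id = id))
  }
  if (is.data.frame(x)) {
    x$trait_id <- id
    return(validate_sumstats(x))
  }
  stop("cannot interpret trait input for ", id)
}

resolve_ld <- function(config) {
  if (is.null(config$ld)) return(NULL)
  if (inherits(config$ld, "ld_matrix")) config$ld else read_ld_matrix(config$ld)
}

# Instrumented univariate MR of one trait pair; returns NULL when no
# instrument survives selection (caller logs and skips).
pair_analysis <- function(exp_ss, out_ss, ld, config) {
  sel <- if (is.null(ld)) {
    rec <- select_by_pvalue(exp_ss$records, config$p_instr)
    failed <- setdiff(exp_ss$records$snp_id, rec$snp_id)
    pruned <- new_selection(
      rec$snp_id,
      data.frame(snp_id = failed, reason = rep("pval", length(failed)),
                 stringsAsFactors = FALSE),
      stats::setNames(f_statistic(exp_ss$records$beta, exp_ss$records$se),
                      exp_ss$records$snp_id)
    )
    pruned <- filter_weak(pruned, config$f_min)
    exclude_confounder_snps(pruned, config$blacklist)
  } else {
    select_instruments(exp_ss, ld, config$p_instr, config$clump_kb,
                       config$clump_r2, config$f_min, config$blacklist)
  }
  if (!length(sel$kept)) return(NULL)
  keep <- exp_ss$records$snp_id %in% sel$kept
  instr <- tryCatch(
    harmonize(exp_ss$records[keep, , drop = FALSE], out_ss),
    mrpath_no_overlap = function(e) NULL
  )
  if (is.null(instr)) return(NULL)
  list(instr = instr, selection = sel)
}

#' Univariate screening stage
#'
#' For every exposure-outcome pair: instrument selection, harmonization,
#' all applicable MR estimators, and the sensitivity battery. IVW (or Wald
#' ratio for single-instrument sets) p-values are FDR-adjusted within each
#' outcome block. Pairs with no surviving instruments are logged and
#' skipped, not fatal.
#'
#' @param config A `"study_config"`.
#' @param traits Which exposure list to screen: `"exposures"` or
#'   `"mediators"`.
#' @return A list with class `"screen_result"`: `results` (one row per
#'   method per pair, with `ivw_pval`, `fdr_pval` and `significant` on the
#'   primary estimate rows), `diagnostics` (one row per pair),
#'   `instruments` (named list of harmonized sets) and `log` (character).
#' @export
run_univariate_screen <- function(config, traits = c("exposures", "mediators")) {
  traits <- match.arg(traits)
  ld <- resolve_ld(config)
  log <- character()
  rows <- list()
  diag_rows <- list()
  instr_sets <- list()
  for (eid in names(config[[traits]])) {
    exp_ss <- load_trait(config[[traits]][[eid]], eid, config$schema)
    for (oid in names(config$outcomes)) {
      out_ss <- load_trait(config$outcomes[[oid]], oid, config$schema)
      pa <- pair_analysis(exp_ss, out_ss, ld, config)
      if (is.null(pa)) {
        log <- c(log, sprintf("skip pair=%s:%s reason=no_instruments", eid, oid))
        next
      }
      instr <- pa$instr
      key <- paste(eid, oid, sep = ":")
      instr_sets[[key]] <- instr
      est <- estimate_all(instr, seed = config$seed)
      est <- cbind(exposure = eid, outcome = oid, est,
                   stringsAsFactors = FALSE)
      rows[[key]] <- est
      sens <- if (n_snp(instr) >= 2) {
        sensitivity_report(instr, n_sim = config$n_sim, seed = config$seed,
                           alpha = config$alpha)
      } else {
        NULL
      }
      diag_rows[[key]] <- data.frame(
        exposure = eid, outcome = oid, n_snp = n_snp(instr),
        q_pval = sens$q_pval %||% NA_real_,
        egger_intercept_pval = sens$egger_intercept_pval %||% NA_real_,
        presso_global_pval = sens$presso_global_pval %||% NA_real_,
        steiger_correct = sens$steiger_correct_direction %||% NA,
        het_or_pleio = if (is.null(sens)) NA else flag_het_pleio(sens, config$alpha),
        stringsAsFactors = FALSE
      )
      for (s in attr(est, "skipped")$method) {
        log <- c(log, sprintf("skip pair=%s method=%s", key, s))
      }
    }
  }
  results <- rbind_rows(rows)
  diagnostics <- rbind_rows(diag_rows)
  if (!is.null(results)) {
    primary <- results$method %in% c("ivw_re", "wald_ratio")
    results$ivw_pval <- NA_real_
    results$fdr_pval <- NA_real_
    results$significant <- NA
    results$ivw_pval[primary] <- results$pval[primary]
    for (oid in unique(results$outcome)) {
      blk <- primary & results$outcome == oid
      results$fdr_pval[blk] <- bh_fdr(results$pval[blk])
    }
    results$significant[primary] <- results$ivw_pval[primary] < config$alpha
  }
  structure(list(results = results, diagnostics = diagnostics,
                 instruments = instr_sets, log = log,
                 config = config, traits = traits),
            class = "screen_result")
}

# Candidates carried into multivariable prioritization: nominally
# significant on the primary estimate and free of heterogeneity or
# horizontal pleiotropy.
gate_candidates <- function(screen, outcome_id) {
  res <- screen$results
  dg <- screen$diagnostics
  primary <- res[!is.na(res$ivw_pval) & res$outcome == outcome_id, ]
  ok <- character()
  for (i in seq_len(nrow(primary))) {
    eid <- primary$exposure[i]
    d <- dg[dg$exposure == eid & dg$outcome == outcome_id, ]
    clean <- nrow(d) == 1 && (is.na(d$het_or_pleio) || !d$het_or_pleio)
    if (primary$significant[i] && clean) ok <- c(ok, eid)
  }
  ok
}

#' Model-averaging prioritization stage
#'
#' Gates candidates (nominally significant primary estimate, no
#' heterogeneity or pleiotropy flags), groups them by panel category, and
#' fits Bayesian model averaging per category and outcome on the union of
#' the candidates' instruments harmonized to the outcome. Groups with fewer
#' than two candidates are skipped with a log entry.
#'
#' @param config A `"study_config"`.
#' @param screen Output of [run_univariate_screen()].
#' @param n_perm Permutations for per-candidate p-values (0 to skip).
#' @return A list with class `"bma_stage"`: `table` (Category, Exposure,
#'   Polyp/outcome, Posterior prob, MACE, MIP, P value), `fits` and `log`.
#' @export
run_bma_stage <- function(config, screen, n_perm = 100) {
  ld <- resolve_ld(config)
  log <- character()
  rows <- list()
  fits <- list()
  categories <- config$categories
  for (oid in names(config$outcomes)) {
    cands <- gate_candidates(screen, oid)
    if (!length(cands)) {
      log <- c(log, sprintf("bma outcome=%s: no candidates after gating", oid))
      next
    }
    cat_of <- if (is.null(categories)) {
      stats::setNames(rep("all", length(cands)), cands)
    } else {
      stats::setNames(categories[cands], cands)
    }
    out_ss <- load_trait(config$outcomes[[oid]], oid, config$schema)
    for (cat_name in unique(cat_of)) {
      members <- names(cat_of)[cat_of == cat_name]
      if (length(members) < 2) {
        log <- c(log, sprintf("bma outcome=%s category=%s: fewer than 2 candidates",
                              oid, cat_name))
        next
      }
      inp <- build_bma_input(config, members, oid, out_ss, ld)
      if (is.null(inp)) {
        log <- c(log, sprintf("bma outcome=%s category=%s: no common instruments",
                              oid, cat_name))
        next
      }
      fit <- suppressWarnings(
        fit_bma(inp, config$prior_prob, config$prior_variance,
                n_iter = config$n_iter, seed = config$seed)
      )
      if (n_perm > 0) {
        fit <- permutation_pvalues(inp, fit, n_perm = max(100, n_perm),
                                   seed = config$seed)
      }
      fits[[paste(oid, cat_name, sep = ":")]] <- fit
      ranked <- rank_candidates(fit, config$mip_threshold)
      best_with <- vapply(ranked$id, function(id) {
        j <- match(id, inp$candidate_ids)
        has <- vapply(strsplit(fit$models$members, ","),
                      function(m) as.character(j) %in% m, logical(1))
        if (any(has)) max(fit$models$posterior_prob[has]) else 0
      }, numeric(1))
      rows[[paste(oid, cat_name, sep = ":")]] <- data.frame(
        category = cat_name, exposure = ranked$id, outcome = oid,
        posterior_prob = best_with, mace = ranked$mace, mip = ranked$mip,
        perm_pval = ranked$perm_pval, important = ranked$important,
        stringsAsFactors = FALSE
      )
    }
  }
  table <- rbind_rows(rows)
  structure(list(table = table, fits = fits, log = log),
            class = "bma_stage")
}

build_bma_input <- function(config, members, oid, out_ss, ld) {
  sets <- list()
  for (eid in members) {
    exp_ss <- load_trait(config$exposures[[eid]], eid, config$schema)
    pa <- pair_analysis(exp_ss, out_ss, ld, config)
    if (!is.null(pa)) sets[[eid]] <- pa$instr
  }
  if (length(sets) < 2) return(NULL)
  snp_union <- unique(unlist(lapply(sets, `[[`, "snp_id")))
  bx <- sapply(members, function(eid) {
    rec <- load_trait(config$exposures[[eid]], eid, config$schema)$records
    rec$beta[match(snp_union, rec$snp_id)]
  })
  sx <- sapply(members, function(eid) {
    rec <- load_trait(config$exposures[[eid]], eid, config$schema)$records
    rec$se[match(snp_union, rec$snp_id)]
  })
  orec <- out_ss$records
  by <- orec$beta[match(snp_union, orec$snp_id)]
  sy <- orec$se[match(snp_union, orec$snp_id)]
  full <- stats::complete.cases(cbind(bx, sx, by, sy))
  if (sum(full) < 3) return(NULL)
  suppressWarnings(bma_input(bx[full, , drop = FALSE], sx[full, , drop = FALSE],
                             by[full], sy[full], members))
}

#' Mediation screening stage
#'
#' For every gated exposure and mediator surviving the univariate screens of
#' the same outcome, fits the exposure-to-mediator univariate MR, combines
#' it with the screened exposure-to-outcome (`beta3`) and
#' mediator-to-outcome (`beta2`) estimates, and screens the pathways for
#' sign consistency.
#'
#' @param config A `"study_config"` with non-empty `mediators`.
#' @param exposure_screen Output of `run_univariate_screen(config,
#'   "exposures")`.
#' @param mediator_screen Output of `run_univariate_screen(config,
#'   "mediators")`.
#' @return A `"mediation_screen"` (see [screen_pathways()]), with the fitted
#'   `beta1` table attached as attribute `"beta1"`.
#' @export
run_mediation_stage <- function(config, exposure_screen, mediator_screen) {
  ld <- resolve_ld(config)
  primary_beta <- function(screen, eid, oid) {
    res <- screen$results
    row <- res[!is.na(res$ivw_pval) & res$exposure == eid & res$outcome == oid, ]
    if (nrow(row) == 1) row$beta else NA_real_
  }
  trips <- list()
  for (oid in names(config$outcomes)) {
    exps <- gate_candidates(exposure_screen, oid)
    meds <- gate_candidates(mediator_screen, oid)
    for (eid in exps) {
      exp_ss <- load_trait(config$exposures[[eid]], eid, config$schema)
      for (mid in meds) {
        med_ss <- load_trait(config$mediators[[mid]], mid, config$schema)
        pa <- pair_analysis(exp_ss, med_ss, ld, config)
        if (is.null(pa) || n_snp(pa$instr) < 2) next
        b1 <- ivw_random_effects(pa$instr)$beta
        trips[[paste(eid, mid, oid, sep = ":")]] <- data.frame(
          exposure_id = eid, mediator_id = mid, outcome_id = oid,
          beta1 = b1,
          beta2 = primary_beta(mediator_screen, mid, oid),
          beta3 = primary_beta(exposure_screen, eid, oid),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  triplets <- rbind_rows(trips)
  if (is.null(triplets)) {
    triplets <- data.frame(exposure_id = character(), mediator_id = character(),
                           outcome_id = character(), beta1 = numeric(),
                           beta2 = numeric(), beta3 = numeric(),
                           stringsAsFactors = FALSE)
  }
  triplets <- triplets[stats::complete.cases(triplets), , drop = FALSE]
  screen_pathways(triplets)
}

#' Run the full study pipeline
#'
#' Univariate screens for exposures (and mediators when supplied), the
#' model-averaging prioritization stage and the mediation stage, assembled
#' into a single report with the run settings.
#'
#' @param config A `"study_config"`.
#' @param n_perm Permutations for the model-averaging p-values.
#' @return A list with class `"study_report"`: `univariate`, `mediator_screen`
#'   (or NULL), `bma`, `mediation` (or NULL), `settings`.
#' @export
run_study <- function(config, n_perm = 100) {
  uni <- run_univariate_screen(config, "exposures")
  med <- if (length(config$mediators)) {
    run_univariate_screen(config, "mediators")
  }
  bma <- run_bma_stage(config, uni, n_perm = n_perm)
  mediation <- if (!is.null(med)) run_mediation_stage(config, uni, med)
  structure(list(
    univariate = uni, mediator_screen = med, bma = bma,
    mediation = mediation,
    settings = config[c("p_instr", "clump_kb", "clump_r2", "f_min", "alpha",
                        "fdr_q", "mip_threshold", "prior_prob",
                        "prior_variance", "n_iter", "n_sim", "seed")]
  ), class = "study_report")
}

#' Write a study report to a directory of TSV tables
#'
#' Emits `univariate.tsv`, `diagnostics.tsv`, `bma.tsv`, `mediation.tsv` (as
#' available) and a `run.json` metadata sidecar with settings and seed.
#'
#' @param report A `"study_report"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, f) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }
  wt(report$univariate$results, "univariate.tsv")
  wt(report$univariate$diagnostics, "diagnostics.tsv")
  wt(report$bma$table, "bma.tsv")
  if (!is.null(report$mediation)) {
    write_mediation_table(report$mediation, file.path(dir, "mediation.tsv"))
  }
  jsonlite::write_json(
    list(settings = report$settings,
         log = c(report$univariate$log, report$bma$log),
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("mrpath"))),
    file.path(dir, "run.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
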