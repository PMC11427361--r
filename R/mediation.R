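# Two-step MR mediation: indirect effect, proportion mediated and
# sign-consistency screening of exposure -> mediator -> outcome pathways.

#' Indirect (mediated) effect
#'
#' Product of the exposure-to-mediator effect (`beta1`) and the
#' mediator-to-outcome effect (`beta2`).
#'
#' @param beta1,beta2 Numeric (vectorized).
#' @return `beta1 * beta2`.
#' @export
#' @examples
#' indirect_effect(0.260, 0.118) # 0.031 to 3 d.p.
indirect_effect <- function(beta1, beta2) beta1 * beta2

#' Delta-method standard error of the indirect effect
#'
#' Optional first-order standard error for `beta1 * beta2`,
#' `sqrt(beta2^2 se1^2 + beta1^2 se2^2)`. Not used by the screening
#' functions by default (the decomposition itself is reported unadorned).
#'
#' @param beta1,se1,beta2,se2 Numeric (vectorized).
#' @return Standard error of the product.
#' @export
indirect_effect_se <- function(beta1, se1, beta2, se2) {
  sqrt(beta2^2 * se1^2 + beta1^2 * se2^2)
}

#' Proportion of the total effect that is mediated
#'
#' `100 * (beta1 * beta2) / beta3`, in percent. May be negative
#' (inconsistent mediation, where the indirect and total effects oppose).
#' Invariant under a joint sign flip of all three effects and antisymmetric
#' under flipping `beta3` alone.
#'
#' @param beta1,beta2 Path effects (exposure to mediator, mediator to
#'   outcome).
#' @param beta3 Total exposure-to-outcome effect (must be nonzero).
#' @return Percent mediated.
#' @export
#' @examples
#' proportion_mediated(-0.189, 0.265, -0.713) # 7.02
proportion_mediated <- function(beta1, beta2, beta3) {
  if (any(beta3 == 0)) stop("proportion mediated undefined: total effect is zero")
  100 * beta1 * beta2 / beta3
}

#' Sign consistency of a mediation pathway
#'
#' `TRUE` when the indirect effect `beta1 * beta2` and the total effect
#' `beta3` are both nonzero and share the same sign; a zero product or zero
#' total effect is not consistent.
#'
#' @param beta1,beta2,beta3 Numeric (vectorized).
#' @return Logical.
#' @export
sign_consistent <- function(beta1, beta2, beta3) {
  ind <- beta1 * beta2
  ind != 0 & beta3 != 0 & sign(ind) == sign(beta3)
}

#' Screen exposure-mediator-outcome pathways
#'
#' Computes the indirect effect, proportion mediated and sign-consistency
#' flag for every supplied triplet, and tallies the consistent pathways in
#' total and per outcome.
#'
#' @param triplets Data frame with columns `exposure_id`, `mediator_id`,
#'   `outcome_id`, `beta1`, `beta2`, `beta3` (typically univariate IVW
#'   estimates for each leg).
#' @return A list with class `"mediation_screen"`: `pathways` (the input plus
#'   `indirect`, `proportion_pct`, `sign_consistent`), `n_consistent`, and
#'   `consistent_by_outcome` (named integer vector).
#' @export
screen_pathways <- function(triplets) {
  req <- c("exposure_id", "mediator_id", "outcome_id", "beta1", "beta2", "beta3")
  stopifnot(all(req %in% names(triplets)))
  out <- triplets
  if (nrow(out)) {
    out$indirect <- indirect_effect(out$beta1, out$beta2)
    out$proportion_pct <- proportion_mediated(out$beta1, out$beta2, out$beta3)
    out$sign_consistent <- sign_consistent(out$beta1, out$beta2, out$beta3)
  } else {
    out$indirect <- numeric()
    out$proportion_pct <- numeric()
    out$sign_consistent <- logical()
  }
  by_outcome <- if (nrow(out)) {
    tapply(out$sign_consistent, out$outcome_id, sum)
  } else {
    integer()
  }
  structure(list(
    pathways = out,
    n_consistent = sum(out$sign_consistent),
    consistent_by_outcome = vapply(by_outcome, as.integer, integer(1))
  ), class = "mediation_screen")
}

#' @export
print.mediation_screen <- function(x, ...) {
  cat("Mediation screen:", nrow(x$pathways), "pathways,",
      x$n_consistent, "sign-consistent\n")
  if (length(x$consistent_by_outcome)) print(x$consistent_by_outcome)
  invisible(x)
}

#' Published mediation worked examples
#'
#' Loads the packaged set of 30 gut-microbiome to immune-trait to polyp
#' mediation pathways (exposure, mediator, outcome, the three path effects
#' `beta1`, `beta2`, `beta3`, and the printed mediator effect and mediated
#' proportion) used as worked examples and regression fixtures. The printed
#' effects are rounded to three decimals, so recomputed products and
#' proportions agree with the printed columns only up to that rounding.
#'
#' @return Data frame with columns `exposure_id`, `mediator_id`,
#'   `outcome_id`, `beta1`, `beta2`, `beta3`, `mediator_effect_printed`,
#'   `mediated_proportion_printed_pct`.
#' @export
mediation_examples <- function() {
  path <- system.file("extdata", "polyp_mediation_pathways.tsv",
                      package = "mrpath", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
}

#' Write a mediation screen as a report table
#'
#' TSV in the standard mediation-report layout: Exposure, Mediator, Outcome,
#' Beta1, Beta2, Beta3, Mediator effect, Mediated Proportion (percent).
#'
#' @param x A `"mediation_screen"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mediation_table <- function(x, path) {
  p <- x$pathways
  out <- data.frame(
    Exposure = p$exposure_id, Mediator = p$mediator_id, Outcome = p$outcome_id,
    Beta1 = p$beta1, Beta2 = p$beta2, Beta3 = p$beta3,
    `Mediator effect` = round(p$indirect, 3),
    `Mediated Proportion` = sprintf("%.2f%%", p$proportion_pct),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
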