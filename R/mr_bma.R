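# Multivariable MR via Bayesian model averaging.
#
# Candidate risk factors enter an inverse-variance-weighted multivariable
# regression of the SNP-outcome effects on the SNP-exposure effect matrix.
# Each subset ("model") of candidates is scored by its closed-form marginal
# likelihood under an independent normal prior on standardized effects;
# model posteriors combine the marginal likelihood with an independent
# Bernoulli inclusion prior per candidate.

#' Assemble the input for multivariable MR model averaging
#'
#' @param beta_x J x d matrix of SNP-exposure effects (one column per
#'   candidate risk factor).
#' @param se_x J x d matrix of their standard errors.
#' @param beta_y Length-J vector of SNP-outcome effects.
#' @param se_y Length-J vector of their standard errors.
#' @param candidate_ids Column labels (default from `beta_x` or `X1..Xd`).
#' @return A list with class `"bma_input"`. Warns when J <= d (fewer
#'   instruments than candidates).
#' @export
bma_input <- function(beta_x, se_x, beta_y, se_y,
                      candidate_ids = colnames(beta_x)) {
  beta_x <- as.matrix(beta_x)
  se_x <- as.matrix(se_x)
  J <- nrow(beta_x)
  d <- ncol(beta_x)
  if (is.null(candidate_ids)) candidate_ids <- paste0("X", seq_len(d))
  stopifnot(nrow(se_x) == J, ncol(se_x) == d,
            length(beta_y) == J, length(se_y) == J,
            all(se_x > 0), all(se_y > 0), d >= 1)
  if (J <= d) warning("fewer instruments than candidates (J <= d)")
  structure(list(beta_x = beta_x, se_x = se_x, beta_y = as.numeric(beta_y),
                 se_y = as.numeric(se_y), candidate_ids = candidate_ids),
            class = "bma_input")
}

model_key <- function(members) paste(members, collapse = ",")

# Marginal log-likelihood of model `members` (integer indices) given
# precomputed sufficient statistics. Effects are standardized; tau2 is the
# prior variance of a standardized effect.
bma_logml <- function(members, G, b, yy, J, tau2) {
  if (length(members) == 0L) {
    return(-J / 2 * log(2 * pi) - yy / 2)
  }
  k <- length(members)
  M <- G[members, members, drop = FALSE] + diag(1 / tau2, k)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdetM <- 2 * sum(log(diag(ch)))
  u <- backsolve(ch, forwardsolve(t(ch), b[members]))
  quad <- yy - sum(b[members] * u)
  -J / 2 * log(2 * pi) - 0.5 * (k * log(tau2) + logdetM) - 0.5 * quad
}

bma_theta <- function(members, G, b, tau2) {
  k <- length(members)
  M <- G[members, members, drop = FALSE] + diag(1 / tau2, k)
  solve(M, b[members])
}

#' Fit multivariable MR by Bayesian model averaging
#'
#' Scores subsets of candidate risk factors by the marginal likelihood of
#' the inverse-variance-weighted multivariable regression of `beta_y` on the
#' included exposure columns, under an independent normal prior of variance
#' `prior_variance` on standardized effects, combined with an independent
#' per-candidate inclusion prior `prior_prob`. All `2^d` models (including
#' the empty model) are enumerated exhaustively when `d <= 16`; for larger
#' panels a seeded shotgun stochastic search (add/delete/swap proposals,
#' `n_iter` proposals) explores the model space and posteriors are
#' normalized over the distinct models visited.
#'
#' Outputs per candidate the marginal inclusion probability (MIP; the sum of
#' posterior probabilities of all models containing the candidate) and the
#' model-averaged causal effect (MACE; the posterior-weighted average of the
#' candidate's conditional effect, zero in models that exclude it).
#'
#' @param input A `"bma_input"`.
#' @param prior_prob Per-candidate prior inclusion probability (default 0.1).
#' @param prior_variance Prior variance of standardized causal effects
#'   (default 0.5).
#' @param n_iter Stochastic-search proposal budget (default 10000; unused
#'   under exhaustive enumeration).
#' @param seed Seed for the stochastic search.
#' @param method `"auto"` (exhaustive when `d <= 16`), `"exhaustive"`, or
#'   `"stochastic"`.
#' @return A list with class `"bma_result"`: `candidates` (data frame `id`,
#'   `mip`, `mace`, `perm_pval` placeholder), `models` (data frame `members`
#'   as comma-separated indices, `size`, `posterior_prob`), and the call
#'   settings. Model posterior probabilities sum to 1 over the enumerated or
#'   visited space.
#' @export
fit_bma <- function(input, prior_prob = 0.1, prior_variance = 0.5,
                    n_iter = 10000, seed = 1, method = c("auto", "exhaustive",
                                                         "stochastic")) {
  stopifnot(inherits(input, "bma_input"),
            prior_prob > 0, prior_prob < 1, prior_variance > 0)
  method <- match.arg(method)
  d <- ncol(input$beta_x)
  J <- nrow(input$beta_x)
  if (method == "auto") method <- if (d <= 16) "exhaustive" else "stochastic"

  ytil <- input$beta_y / input$se_y
  Xtil <- input$beta_x / input$se_y  # row-wise inverse-variance scaling
  scale <- sqrt(colMeans(Xtil^2))
  if (any(scale == 0)) stop("candidate with all-zero instrument effects")
  Z <- sweep(Xtil, 2, scale, "/")
  G <- crossprod(Z)
  b <- drop(crossprod(Z, ytil))
  yy <- sum(ytil^2)
  tau2 <- prior_variance
  lp_in <- log(prior_prob)
  lp_out <- log(1 - prior_prob)

  score <- function(members) {
    bma_logml(members, G, b, yy, J, tau2) +
      length(members) * lp_in + (d - length(members)) * lp_out
  }

  if (method == "exhaustive") {
    models <- lapply(0:(2^d - 1), function(m) which(bitwAnd(m, 2^(0:(d - 1))) > 0))
    keys <- vapply(models, model_key, character(1))
    logpost <- vapply(models, score, numeric(1))
  } else {
    set.seed(seed)
    env <- new.env(hash = TRUE, parent = emptyenv())
    cur <- sort(sample.int(d, size = max(1, stats::rbinom(1, d, prior_prob))))
    remember <- function(mem) {
      key <- paste0("m:", model_key(mem))  # env keys must be non-empty
      if (is.null(env[[key]])) env[[key]] <- list(members = mem, lp = score(mem))
      env[[key]]$lp
    }
    lp_cur <- remember(cur)
    remember(integer(0))
    for (i in seq_len(n_iter)) {
      prop <- propose_model(cur, d)
      lp_prop <- remember(prop)
      if (log(stats::runif(1)) < lp_prop - lp_cur) {
        cur <- prop
        lp_cur <- lp_prop
      }
    }
    visited <- as.list(env)
    models <- lapply(visited, `[[`, "members")
    keys <- vapply(models, model_key, character(1))
    logpost <- vapply(visited, `[[`, numeric(1), "lp")
  }

  if (!any(is.finite(logpost))) {
    stop("non-finite marginal likelihood for every model")
  }
  post <- exp(logpost - max(logpost[is.finite(logpost)]))
  post[!is.finite(post)] <- 0
  post <- post / sum(post)

  mip <- numeric(d)
  mace <- numeric(d)
  for (i in seq_along(models)) {
    mem <- models[[i]]
    if (length(mem) == 0L || post[i] == 0) next
    mip[mem] <- mip[mem] + post[i]
    theta_std <- bma_theta(mem, G, b, tau2)
    mace[mem] <- mace[mem] + post[i] * theta_std / scale[mem]
  }

  ord <- order(post, decreasing = TRUE)
  structure(list(
    candidates = data.frame(id = input$candidate_ids, mip = mip, mace = mace,
                            perm_pval = NA_real_, stringsAsFactors = FALSE),
    models = data.frame(members = keys[ord],
                        size = vapply(models[ord], length, integer(1)),
                        posterior_prob = post[ord], stringsAsFactors = FALSE),
    prior_prob = prior_prob, prior_variance = prior_variance,
    method = method, n_iter = n_iter, seed = seed
  ), class = "bma_result")
}

propose_model <- function(cur, d) {
  out <- setdiff(seq_len(d), cur)
  move <- sample(c("add", "delete", "swap"), 1)
  if (move == "add" && length(out)) {
    sort(c(cur, out[sample.int(length(out), 1)]))
  } else if (move == "delete" && length(cur)) {
    sort(cur[-sample.int(length(cur), 1)])
  } else if (move == "swap" && length(cur) && length(out)) {
    sort(c(cur[-sample.int(length(cur), 1)], out[sample.int(length(out), 1)]))
  } else {
    cur
  }
}

#' @export
print.bma_result <- function(x, ...) {
  cat("MR-BMA (", x$method, "):", nrow(x$models), "models scored\n")
  print(x$candidates[order(-x$candidates$mip), ], row.names = FALSE)
  invisible(x)
}

#' Rank candidates by marginal inclusion probability
#'
#' @param result A `"bma_result"`.
#' @param mip_threshold Candidates with MIP strictly above this are flagged
#'   as high importance (default 0.1).
#' @return The `candidates` data frame sorted by descending MIP (ties broken
#'   by candidate id) with a logical `important` column.
#' @export
rank_candidates <- function(result, mip_threshold = 0.1) {
  cand <- result$candidates
  cand <- cand[order(-cand$mip, cand$id), , drop = FALSE]
  cand$important <- cand$mip > mip_threshold
  rownames(cand) <- NULL
  cand
}

#' Permutation p-values for candidate inclusion
#'
#' Re-fits the model averaging on outcome-permuted data (`beta_y`/`se_y`
#' rows permuted jointly) `n_perm` times and reports, per candidate, the
#' rank-based exceedance probability of its observed MIP with +1 smoothing,
#' so the smallest attainable p-value is `1/(n_perm + 1)`.
#'
#' @param input The `"bma_input"` used for the observed fit.
#' @param result The observed `"bma_result"`.
#' @param n_perm Number of permutations (default 100, minimum 100).
#' @param seed Seed for the permutations.
#' @return The `result` with `candidates$perm_pval` filled in.
#' @export
permutation_pvalues <- function(input, result, n_perm = 100, seed = 1) {
  stopifnot(n_perm >= 100)
  set.seed(seed)
  J <- nrow(input$beta_x)
  obs <- result$candidates$mip
  exceed <- numeric(length(obs))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(J)
    perm <- bma_input(input$beta_x, input$se_x,
                      input$beta_y[idx], input$se_y[idx],
                      input$candidate_ids)
    fit <- suppressWarnings(fit_bma(perm, result$prior_prob,
                                    result$prior_variance,
                                    n_iter = result$n_iter,
                                    seed = seed + b, method = result$method))
    exceed <- exceed + (fit$candidates$mip >= obs)
  }
  result$candidates$perm_pval <- (1 + exceed) / (n_perm + 1)
  result
}
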