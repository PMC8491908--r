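#' Multi-study Bayesian fine mapping
#'
#' Fits the random-effects multi-study fine-mapping model to one locus:
#' every causal configuration with 1..`max_causal` causal SNPs is scored by
#' `log P(S | C) + log P(C)`, posteriors are normalized over the enumerated
#' configurations, per-SNP posterior inclusion probabilities (PIPs) are
#' accumulated, and the minimal set of SNPs containing all causal SNPs with
#' posterior probability at least `rho_star` is constructed greedily in
#' descending-PIP order with exact compatible-configuration mass accounting.
#'
#' The likelihood treats the stacked Z-scores as
#' `S ~ N(0, Sigma + Sigma Sigma_C Sigma)`: per-study causal effects are
#' drawn around a shared mean effect (variance `ncp_scale^2`, scaled up for
#' studies larger than the smallest) with between-study heterogeneity
#' variance `tau_sq`, and LD propagates causal non-centrality to correlated
#' SNPs.  With one study and `tau_sq = 0` the model reduces to single-study
#' CAVIAR-type fine mapping.
#'
#' @param locus a [multistudy_locus()].
#' @param tau_sq between-study heterogeneity variance tau^2 (default 0.52).
#' @param ncp_scale standard deviation sigma of a causal SNP's mean
#'   non-centrality parameter in the smallest study (default 5.2, the
#'   genome-wide-significance Z-score).
#' @param gamma per-SNP prior causal probability (default 0.01).
#' @param max_causal maximum number of causal SNPs per configuration
#'   (default 3).
#' @param rho_star confidence level for the causal set (default 0.95).
#' @param path likelihood path: `"lowrank"` (default; handles rank-deficient
#'   LD), `"fast"` (Woodbury, full-rank LD), or `"dense"` (reference).
#' @param include_null also enumerate the all-zero configuration and include
#'   it in the normalization (default FALSE: the tool is meant for loci with
#'   a significant signal).
#' @param epsilon legacy ridge for non-causal diagonal entries of the causal
#'   covariance; only honoured by the dense path.
#' @param truncation eigenvalue truncation for the low-rank path.
#' @param lowrank_variant,m_factor see [loglik_lowrank()].
#' @param warn_signs warn when many high-LD SNP pairs have opposite-sign
#'   Z-scores (possible allele-harmonization problem).
#'
#' @return An object of class `"finemap"`; a list with, among others,
#'   `snp_ids`, `pip` (named per-SNP inclusion probabilities), `set`
#'   (the rho*-confidence set, descending PIP), `set_prob` (exact posterior
#'   mass of configurations compatible with the set), `configs` (list of
#'   causal index vectors), `log_post` (unnormalized) and
#'   `norm_log_post` (normalized, log scale).
#' @seealso [confidence_set()], [rank_until_causal()], [sim_locus()]
#' @examples
#' ld <- ar1_ld(10, 0.8)
#' z <- drop(ld %*% c(6, rep(0, 9))) + rnorm(10, 0, 0.1)
#' fit <- finemap(multistudy_locus(z, ld), max_causal = 2)
#' fit$set
#' @export
finemap <- function(locus, tau_sq = 0.52, ncp_scale = 5.2, gamma = 0.01,
                    max_causal = 3L, rho_star = 0.95,
                    path = c("lowrank", "fast", "dense"),
                    include_null = FALSE, epsilon = 0, truncation = 1e-8,
                    lowrank_variant = c("exact", "printed"), m_factor = TRUE,
                    warn_signs = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  if (!inherits(locus, "multistudy_locus"))
    stop("'locus' must be a multistudy_locus")
  path <- match.arg(path)
  lowrank_variant <- match.arg(lowrank_variant)
  if (!is.numeric(rho_star) || length(rho_star) != 1L ||
      rho_star <= 0 || rho_star > 1)
    stop("'rho_star' must be in (0, 1]")
  M <- locus$M; Q <- locus$Q
  K <- as.integer(max_causal)
  if (K > M) K <- M
  if (warn_signs) check_sign_consistency(locus)

  configs <- enumerate_configs(M, K)
  kk <- vapply(configs, length, 1L)

  if (path == "dense") {
    ll <- vapply(configs, function(J) {
      loglik_dense(locus, build_causal_covariance(
        config_indices_to_binary(J, M), Q, tau_sq, ncp_scale,
        locus$sample_sizes, epsilon = epsilon))
    }, 1.0)
  } else {
    cache <- locus_precompute(locus, path, truncation = truncation,
                              lowrank_variant = lowrank_variant,
                              m_factor = m_factor)
    ll <- config_scan(cache, configs, tau_sq, ncp_scale, locus$sample_sizes)
  }
  if (include_null) {
    ll0 <- if (path == "dense")
      loglik_dense(locus, build_causal_covariance(
        rep(0, M), Q, tau_sq, ncp_scale, locus$sample_sizes,
        epsilon = epsilon))
    else -0.5 * (cache$dim0 * log(2 * pi) + cache$logdet0 + cache$ssq)
    configs <- c(configs, list(integer(0)))
    kk <- c(kk, 0L)
    ll <- c(ll, ll0)
  }
  if (any(!is.finite(ll))) {
    bad <- which(!is.finite(ll))[1L]
    stop("non-finite log-likelihood for configuration {",
         paste(locus$snp_ids[configs[[bad]]], collapse = ", "), "}")
  }

  log_prior <- kk * log(gamma) + (M - kk) * log1p(-gamma)
  lp <- ll + log_prior
  lse <- logsumexp(lp)
  nlp <- lp - lse
  post <- exp(nlp)

  pip <- numeric(M)
  for (i in seq_along(configs)) pip[configs[[i]]] <- pip[configs[[i]]] + post[i]
  pip <- pmin(pip, 1)
  names(pip) <- locus$snp_ids

  cs <- greedy_confidence_set(configs, post, pip, rho_star)

  structure(list(
    snp_ids = locus$snp_ids, M = M, Q = Q, labels = locus$labels,
    configs = configs, k = kk, loglik = ll, log_prior = log_prior,
    log_post = lp, norm_log_post = nlp, pip = pip,
    set = locus$snp_ids[cs$members], set_idx = cs$members,
    set_prob = cs$prob, rho_star = rho_star,
    params = list(tau_sq = tau_sq, ncp_scale = ncp_scale, gamma = gamma,
                  max_causal = K, path = path, include_null = include_null,
                  epsilon = epsilon, truncation = truncation,
                  lowrank_variant = lowrank_variant, m_factor = m_factor),
    runtime = proc.time()[["elapsed"]] - t0),
    class = "finemap")
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# SNPs ranked by descending PIP, ties broken by input order.
pip_order <- function(pip) order(-pip, seq_along(pip))

# Greedy rho*-set: rank SNPs by PIP; a configuration becomes compatible once
# the set contains its worst-ranked member, so the exact compatible mass of
# the top-n set is a cumulative sum over configurations' max ranks.
greedy_confidence_set <- function(configs, post, pip, rho_star) {
  M <- length(pip)
  ord <- pip_order(pip)
  rank_of <- integer(M); rank_of[ord] <- seq_len(M)
  maxrank <- vapply(seq_along(configs), function(i) {
    J <- configs[[i]]
    if (length(J) == 0L) 0L else max(rank_of[J])
  }, 1L)
  mass_by_rank <- vapply(seq_len(M), function(n) sum(post[maxrank <= n]), 1.0)
  n_star <- match(TRUE, mass_by_rank >= rho_star - 1e-12)
  if (is.na(n_star)) n_star <- M            # total mass always qualifies
  list(members = ord[seq_len(n_star)], prob = mass_by_rank[n_star])
}

#' Recompute the confidence set at a different confidence level
#'
#' Rebuilds the greedy descending-PIP causal set from a fitted object's
#' posterior table for a new `rho_star`, without refitting.  The reported
#' probability is the exact posterior mass of the configurations whose
#' causal SNPs all lie inside the set (not the sum of PIPs).
#'
#' @param fit a [finemap()] object.
#' @param rho_star confidence level in (0, 1].
#' @return list with `set_members` (SNP ids, descending PIP) and `set_prob`.
#' @export
confidence_set <- function(fit, rho_star = 0.95) {
  stopifnot(inherits(fit, "finemap"))
  if (!is.numeric(rho_star) || length(rho_star) != 1L ||
      rho_star <= 0 || rho_star > 1)
    stop("'rho_star' must be in (0, 1]")
  cs <- greedy_confidence_set(fit$configs, exp(fit$norm_log_post), fit$pip,
                              rho_star)
  list(set_members = fit$snp_ids[cs$members], set_prob = cs$prob)
}

# Exact posterior mass of configurations compatible with an arbitrary SNP
# set (all causal indices inside `members`).  Used by tests and summaries.
compatible_mass <- function(fit, members) {
  if (is.character(members)) members <- match(members, fit$snp_ids)
  inside <- logical(fit$M); inside[members] <- TRUE
  post <- exp(fit$norm_log_post)
  sum(post[vapply(fit$configs, function(J) all(inside[J]), TRUE)])
}

#' SNPs inspected before all true causal SNPs are found
#'
#' Simulation metric: ranks SNPs by descending PIP (ties broken by input
#' order) and returns how many must be taken, from the top, until every true
#' causal SNP is included.
#'
#' @param fit a [finemap()] object.
#' @param truth binary causal-status vector of length M, or integer indices,
#'   or SNP identifiers of the true causal SNPs.
#' @return integer count.
#' @export
rank_until_causal <- function(fit, truth) {
  stopifnot(inherits(fit, "finemap"))
  if (is.character(truth)) {
    idx <- match(truth, fit$snp_ids)
    if (any(is.na(idx))) stop("unknown SNP id in 'truth'")
  } else if (length(truth) == fit$M && all(truth %in% c(0, 1))) {
    idx <- which(truth == 1)
  } else {
    idx <- as.integer(truth)
    if (any(idx < 1L | idx > fit$M)) stop("'truth' indices out of range")
  }
  if (length(idx) == 0L) stop("'truth' contains no causal SNP")
  rank_of <- integer(fit$M); rank_of[pip_order(fit$pip)] <- seq_len(fit$M)
  max(rank_of[idx])
}

#' @export
print.finemap <- function(x, ...) {
  cat("Multi-study fine mapping (", x$params$path, " path)\n", sep = "")
  cat(sprintf("  %d SNPs x %d studies; up to %d causal; %d configurations\n",
              x$M, x$Q, x$params$max_causal, length(x$configs)))
  cat(sprintf("  tau^2 = %g, sigma = %g, gamma = %g\n",
              x$params$tau_sq, x$params$ncp_scale, x$params$gamma))
  cat(sprintf("  %.0f%% confidence set (%d SNPs, posterior mass %.4f):\n",
              100 * x$rho_star, length(x$set), x$set_prob))
  cat("   ", paste(utils::head(x$set, 12L), collapse = ", "),
      if (length(x$set) > 12L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
summary.finemap <- function(object, n_top = 10L, ...) {
  post <- exp(object$norm_log_post)
  res <- list(
    M = object$M, Q = object$Q, params = object$params,
    rho_star = object$rho_star, set = object$set,
    set_prob = object$set_prob,
    expected_n_causal = sum(object$k * post),
    top = data.frame(
      snp = object$snp_ids[pip_order(object$pip)][seq_len(min(n_top, object$M))],
      pip = unname(sort(object$pip, decreasing = TRUE))[seq_len(min(n_top, object$M))],
      row.names = NULL))
  class(res) <- "summary.finemap"
  res
}

#' @export
print.summary.finemap <- function(x, ...) {
  cat(sprintf("Fine-mapped locus: %d SNPs x %d studies\n", x$M, x$Q))
  cat(sprintf("Expected number of causal SNPs: %.2f\n", x$expected_n_causal))
  cat(sprintf("%.0f%% confidence set: %d SNPs (posterior mass %.4f)\n",
              100 * x$rho_star, length(x$set), x$set_prob))
  cat("Top SNPs by posterior inclusion probability:\n")
  print(format(x$top, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
coef.finemap <- function(object, ...) object$pip

#' @export
plot.finemap <- function(x, ...) {
  inset <- x$snp_ids %in% x$set
  graphics::plot(seq_len(x$M), x$pip, type = "h",
                 col = ifelse(inset, "firebrick", "grey40"),
                 xlab = "SNP index", ylab = "Posterior inclusion probability",
                 ylim = c(0, 1), ...)
  graphics::points(which(inset), x$pip[inset], pch = 19, col = "firebrick")
  graphics::legend("topright", bty = "n", pch = c(19, NA), lty = c(NA, 1),
                   col = c("firebrick", "grey40"),
                   legend = c(sprintf("%.0f%% set", 100 * x$rho_star),
                              "other SNPs"))
  invisible(x)
}
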