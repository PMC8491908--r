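# Independent oracles the implementation is tested against.  Everything here
# is deliberately coded from first principles (eigendecompositions and
# elementwise covariance construction) rather than through the package's own
# Cholesky/Woodbury machinery.

# random positive-definite correlation matrix
rand_corr <- function(M, jitter = 1) {
  A <- matrix(rnorm(M * M), M)
  cov2cor(crossprod(A) + jitter * diag(M))
}

# MVN log-density at x with mean 0, covariance V, via eigendecomposition
dmvn_eigen <- function(x, V) {
  eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
  stopifnot(all(eg$values > 0))
  y <- drop(crossprod(eg$vectors, x))
  -0.5 * (length(x) * log(2 * pi) + sum(log(eg$values)) + sum(y^2 / eg$values))
}

# block-diagonal LD of a multi-study locus
blockdiag_ld <- function(locus) {
  M <- locus$M; Q <- locus$Q
  sig <- matrix(0, M * Q, M * Q)
  for (q in seq_len(Q)) {
    jj <- (q - 1L) * M + seq_len(M)
    sig[jj, jj] <- locus$ld[[q]]
  }
  sig
}

# Elementwise construction of the random-effects causal covariance:
# entry ((q1,m1),(q2,m2)) is nonzero only for m1 == m2 causal, equal to
# tau^2 + s_q^2 within a study and s_q1 s_q2 across studies.
causal_cov_elementwise <- function(causal_idx, M, Q, tau_sq, ncp_scale,
                                   sample_sizes = NULL) {
  s <- if (is.null(sample_sizes)) rep(ncp_scale, Q)
       else ncp_scale * sqrt(sample_sizes / min(sample_sizes))
  V <- matrix(0, M * Q, M * Q)
  for (m in causal_idx) for (q1 in seq_len(Q)) for (q2 in seq_len(Q)) {
    i <- (q1 - 1L) * M + m; j <- (q2 - 1L) * M + m
    V[i, j] <- s[q1] * s[q2] + if (q1 == q2) tau_sq else 0
  }
  V
}

# Brute-force posterior over ALL nonempty configurations (k = 1..M) of a
# multi-study locus, using the dense MVN density above.
brute_force_posterior <- function(locus, tau_sq = 0.52, ncp_scale = 5.2,
                                  gamma = 0.01, max_causal = locus$M) {
  M <- locus$M
  sig <- blockdiag_ld(locus)
  S <- unlist(locus$z, use.names = FALSE)
  configs <- list(); lp <- numeric(0)
  for (k in seq_len(max_causal)) {
    cmb <- utils::combn(M, k)
    for (j in seq_len(ncol(cmb))) {
      J <- cmb[, j]
      Sc <- causal_cov_elementwise(J, M, locus$Q, tau_sq, ncp_scale,
                                   locus$sample_sizes)
      ll <- dmvn_eigen(S, sig + sig %*% Sc %*% sig)
      configs <- c(configs, list(J))
      lp <- c(lp, ll + k * log(gamma) + (M - k) * log(1 - gamma))
    }
  }
  post <- exp(lp - max(lp)); post <- post / sum(post)
  pip <- numeric(M)
  for (i in seq_along(configs)) pip[configs[[i]]] <- pip[configs[[i]]] + post[i]
  list(configs = configs, post = post, pip = pip)
}

# Independently coded single-study fine-mapping posterior: configurations of
# k <= max_causal causal SNPs, likelihood N(S; 0, Sigma + sigma^2 *
# Sigma[,J] Sigma[J,]), Bernoulli(gamma) prior.
single_study_reference <- function(z, ld, sigma = 5.2, gamma = 0.01,
                                   max_causal = 3L) {
  M <- length(z)
  configs <- list(); lp <- numeric(0)
  for (k in seq_len(min(max_causal, M))) {
    cmb <- utils::combn(M, k)
    for (j in seq_len(ncol(cmb))) {
      J <- cmb[, j]
      V <- ld + sigma^2 * ld[, J, drop = FALSE] %*% ld[J, , drop = FALSE]
      ll <- dmvn_eigen(z, V)
      configs <- c(configs, list(J))
      lp <- c(lp, ll + k * log(gamma) + (M - k) * log(1 - gamma))
    }
  }
  post <- exp(lp - max(lp)); post <- post / sum(post)
  pip <- numeric(M)
  for (i in seq_along(configs)) pip[configs[[i]]] <- pip[configs[[i]]] + post[i]
  list(configs = configs, post = post, pip = pip)
}

# Exact minimal rho*-set size by exhaustive search over SNP subsets in
# increasing size (feasible for M <= 10).
exhaustive_min_set_size <- function(fit, rho) {
  post <- exp(fit$norm_log_post)
  M <- fit$M
  for (s in seq_len(M)) {
    subs <- utils::combn(M, s)
    for (j in seq_len(ncol(subs))) {
      inside <- logical(M); inside[subs[, j]] <- TRUE
      mass <- sum(post[vapply(fit$configs,
                              function(J) all(inside[J]), TRUE)])
      if (mass >= rho - 1e-12) return(s)
    }
  }
  M
}

# small random multi-study locus with a planted causal signal
rand_locus <- function(M, Q, n_causal = 1L, tau_sq = 0.52, ncp = 5.2,
                       sample_sizes = NULL) {
  ld <- replicate(Q, rand_corr(M), simplify = FALSE)
  J <- sort(sample.int(M, n_causal))
  z <- lapply(seq_len(Q), function(q) {
    lc <- numeric(M); lc[J] <- ncp
    drop(ld[[q]] %*% lc) + drop(t(chol(ld[[q]])) %*% rnorm(M))
  })
  list(locus = multistudy_locus(z, ld, sample_sizes = sample_sizes),
       truth = J)
}
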