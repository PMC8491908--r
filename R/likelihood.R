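# Likelihood of the observed Z-scores under a causal configuration.
#
# Model: stacking the Q studies' Z-score vectors (study-major) gives
#   S ~ N(0, Sigma + Sigma Sigma_C Sigma)
# where Sigma is block-diagonal with the per-study LD matrices and Sigma_C is
# the random-effects causal covariance (build_causal_covariance).  Three
# evaluation paths:
#   * dense   - literal MQ x MQ computation; the oracle the others are tested
#               against; requires invertible LD.
#   * fast    - factors Sigma out and applies the Woodbury and Sylvester
#               identities so per-configuration cost is O((KQ)^3) after a
#               per-locus precomputation; requires invertible LD.
#   * lowrank - transforms each study's statistics through the retained
#               eigencomponents of its LD matrix; exact for full-rank LD (up
#               to a configuration-independent constant) and well-defined for
#               rank-deficient LD.  The default.

#' Dense log-likelihood of a multi-study locus
#'
#' Evaluates `log N(S; 0, Sigma + Sigma Sigma_C Sigma)` by direct dense
#' computation on the full MQ x MQ covariance.  Used as the reference
#' implementation for the fast and low-rank paths; cost is cubic in MQ.
#'
#' @param locus a [multistudy_locus()].
#' @param causal_cov MQ x MQ causal covariance from
#'   [build_causal_covariance()] (study-major layout).
#' @return log-likelihood (scalar).
#' @export
loglik_dense <- function(locus, causal_cov) {
  MQ <- locus$M * locus$Q
  if (!is.matrix(causal_cov) || any(dim(causal_cov) != MQ))
    stop("'causal_cov' must be ", MQ, " x ", MQ)
  sig <- matrix(0, MQ, MQ)
  for (q in seq_len(locus$Q)) {
    jj <- (q - 1L) * locus$M + seq_len(locus$M)
    sig[jj, jj] <- locus$ld[[q]]
  }
  V <- sig + sig %*% causal_cov %*% sig
  S <- unlist(locus$z, use.names = FALSE)
  ch <- tryCatch(chol(V), error = function(e)
    stop("joint covariance is singular (rank-deficient LD?); ",
         "use the low-rank path (path = \"lowrank\")", call. = FALSE))
  y <- backsolve(ch, S, transpose = TRUE)
  -0.5 * (MQ * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(y^2))
}

#' Eigendecomposition of an LD matrix for the low-rank path
#'
#' Symmetric eigendecomposition `Sigma = W Omega W'` with small eigenvalues
#' (and their eigenvectors) dropped, plus the transformed statistics
#' `S' = Omega^{-1/2} W' S` when Z-scores are supplied.  Eigenvector signs
#' follow a deterministic convention (largest-magnitude component positive)
#' so results are reproducible across LAPACK builds.
#'
#' @param ld_matrix symmetric LD matrix.
#' @param z optional Z-score vector used to form `transformed_stats`.
#' @param truncation relative eigenvalue threshold: components with
#'   eigenvalue `<= truncation * max(eigenvalue)` are dropped
#'   (default 1e-8).
#' @return list with `eigenvectors` (M x rank), `eigenvalues` (length rank),
#'   `rank`, `projector` (`B = Omega^{-1/2} W'`, rank x M) and, when `z` is
#'   given, `transformed_stats`.
#' @export
eigen_ld <- function(ld_matrix, z = NULL, truncation = 1e-8) {
  ld_matrix <- as.matrix(ld_matrix)
  if (nrow(ld_matrix) != ncol(ld_matrix) ||
      max(abs(ld_matrix - t(ld_matrix))) > 1e-6)
    stop("'ld_matrix' must be symmetric")
  eg <- eigen((ld_matrix + t(ld_matrix)) / 2, symmetric = TRUE)
  keep <- eg$values > truncation * max(eg$values)
  W <- eg$vectors[, keep, drop = FALSE]
  # sign convention: largest-|.| component of each eigenvector positive
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  lam <- eg$values[keep]
  out <- list(eigenvectors = W, eigenvalues = lam, rank = sum(keep),
              projector = t(W) / sqrt(lam))
  if (!is.null(z)) out$transformed_stats <- drop(out$projector %*% z)
  out
}

# Per-locus precomputation shared by every configuration.
#
# The per-configuration correction term has the common form
#   corr = v' Sigma_cc (I + G Sigma_cc)^{-1} v
# with Sigma_cc = T (x) I_k the causal block of Sigma_C and G the causal
# block of a per-study Gram matrix H_q; writing P = Sigma_cc^{1/2} this is
#   corr = (P v)' (I + P G P)^{-1} (P v),   |I + G Sigma_cc| = |I + P G P|,
# and I + P G P is symmetric PD, so one Cholesky per configuration does both
# the determinant and the solve.
#   fast path:    quad = S'(I + Sigma_C Sigma)^{-1} Sigma^{-1} S with
#                 (I + UV)^{-1} = I - U (I + VU)^{-1} V, U = Sigma_C[, idx],
#                 V = Sigma[idx, ]; then S'U = S[idx]' Sigma_cc and
#                 V Sigma^{-1} S = S[idx], so H_q = Sigma_q and v = S[idx].
#   lowrank path: H_q = reconstructed Sigma_q from retained components,
#                 v = (W_r W_r' S)[idx] (projection of S)
locus_precompute <- function(locus, path = c("lowrank", "fast"),
                             truncation = 1e-8,
                             lowrank_variant = c("exact", "printed"),
                             m_factor = TRUE) {
  path <- match.arg(path)
  lowrank_variant <- match.arg(lowrank_variant)
  M <- locus$M; Q <- locus$Q
  H <- vector("list", Q); lvec <- vector("list", Q); rvec <- vector("list", Q)
  ssq <- 0; logdet0 <- 0; dim0 <- 0L
  if (path == "fast") {
    for (q in seq_len(Q)) {
      Sq <- locus$z[[q]]; Lq <- locus$ld[[q]]
      ch <- tryCatch(chol(Lq), error = function(e)
        stop("LD matrix of study ", q, " is not positive definite; ",
             "use the low-rank path (path = \"lowrank\")", call. = FALSE))
      H[[q]] <- Lq
      lvec[[q]] <- rvec[[q]] <- Sq
      sinv <- backsolve(ch, backsolve(ch, Sq, transpose = TRUE))
      ssq <- ssq + sum(Sq * sinv)           # S' Sigma^{-1} S
      logdet0 <- logdet0 + 2 * sum(log(diag(ch)))
      dim0 <- dim0 + M
    }
  } else {
    scale_m <- 1
    for (q in seq_len(Q)) {
      eg <- eigen_ld(locus$ld[[q]], z = locus$z[[q]], truncation = truncation)
      W <- eg$eigenvectors; lam <- eg$eigenvalues
      wz <- drop(crossprod(W, locus$z[[q]]))
      if (lowrank_variant == "exact") {
        # Cov(S') = I + D Sigma_C D' with D = Omega^{1/2} W' (retained rows)
        H[[q]] <- W %*% (lam * t(W))
        lvec[[q]] <- rvec[[q]] <- drop(W %*% wz)
      } else {
        # as-printed variant: Cov(S') = I + m B Sigma_C B', B = Omega^{-1/2} W'
        H[[q]] <- W %*% (t(W) / lam)
        lvec[[q]] <- rvec[[q]] <- drop(W %*% (wz / lam))
        if (m_factor) scale_m <- M
      }
      ssq <- ssq + sum(wz^2 / lam)          # S'' S'
      dim0 <- dim0 + eg$rank
    }
    if (lowrank_variant == "printed") attr(H, "scale_m") <- scale_m
  }
  list(path = path, M = M, Q = Q, H = H, l = lvec, r = rvec,
       ssq = ssq, logdet0 = logdet0, dim0 = dim0,
       scale_m = if (path == "lowrank" && lowrank_variant == "printed" &&
                     m_factor) M else 1)
}

# Symmetric square root of the study covariance T, expanded to kQ x kQ as
# T^{1/2} (x) I_k for k = 1..K.  Returned with per-k index templates.
config_scan_setup <- function(cache, K, tau_sq, ncp_scale, sample_sizes) {
  Tm <- cache$scale_m * study_covariance(cache$Q, tau_sq, ncp_scale,
                                         sample_sizes)
  eg <- eigen(Tm, symmetric = TRUE)
  Th <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  P <- vector("list", K)
  for (k in seq_len(K)) P[[k]] <- Th %x% diag(k)
  list(P = P, Tm = Tm)
}

# Log-likelihood for each configuration (list of causal index vectors).
config_scan <- function(cache, configs, tau_sq, ncp_scale,
                        sample_sizes = NULL) {
  K <- max(vapply(configs, length, 1L))
  setup <- config_scan_setup(cache, K, tau_sq, ncp_scale, sample_sizes)
  Q <- cache$Q
  base <- -0.5 * (cache$dim0 * log(2 * pi) + cache$logdet0 + cache$ssq)
  ll <- numeric(length(configs))
  H <- cache$H; lv <- cache$l; rv <- cache$r
  for (i in seq_along(configs)) {
    J <- configs[[i]]
    k <- length(J)
    kQ <- k * Q
    G <- matrix(0, kQ, kQ)
    lx <- numeric(kQ); rx <- numeric(kQ)
    for (q in seq_len(Q)) {
      jj <- (q - 1L) * k + seq_len(k)
      G[jj, jj] <- H[[q]][J, J]
      lx[jj] <- lv[[q]][J]
      rx[jj] <- rv[[q]][J]
    }
    P <- setup$P[[k]]
    A <- P %*% G %*% P
    diag(A) <- diag(A) + 1
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) {                      # ill-conditioned small system
      ll[i] <- NA_real_
      next
    }
    yl <- backsolve(ch, P %*% lx, transpose = TRUE)
    yr <- if (identical(lv, rv)) yl
          else backsolve(ch, P %*% rx, transpose = TRUE)
    ll[i] <- base - sum(log(diag(ch))) + 0.5 * sum(yl * yr)
  }
  ll
}

#' Fast log-likelihood via Woodbury/Sylvester identities
#'
#' Returns the same value as [loglik_dense()] but factors the LD matrix out
#' of the joint covariance so that, after a per-locus precomputation
#' (`S' Sigma^{-1}`, `log|Sigma|`), each configuration costs O((KQ)^3)
#' instead of O((MQ)^3).  Requires full-rank LD.
#'
#' @inheritParams loglik_dense
#' @param config integer vector of causal SNP indices (or binary vector).
#' @param tau_sq between-study heterogeneity variance.
#' @param ncp_scale causal NCP standard deviation for the smallest study.
#' @param cache optional precomputation from an earlier call on the same
#'   locus (internal use).
#' @return log-likelihood (scalar).
#' @export
loglik_fast <- function(locus, config, tau_sq = 0.52, ncp_scale = 5.2,
                        cache = NULL) {
  J <- config_as_indices(config, locus$M)
  if (is.null(cache)) cache <- locus_precompute(locus, "fast")
  ll <- config_scan(cache, list(J), tau_sq, ncp_scale, locus$sample_sizes)
  if (is.na(ll)) {
    warning("ill-conditioned Woodbury system; falling back to dense path")
    ll <- loglik_dense(locus, build_causal_covariance(
      config_indices_to_binary(J, locus$M), locus$Q, tau_sq, ncp_scale,
      locus$sample_sizes))
  }
  ll
}

#' Low-rank log-likelihood via transformed statistics
#'
#' Evaluates the model on each study's eigendecomposed LD matrix: with
#' `Sigma_q = W Omega W'` and `S'_q = Omega^{-1/2} W' S_q` restricted to the
#' retained components, the transformed statistics are exactly
#' `S' ~ N(0, I + D Sigma_C D')` with `D = Omega^{1/2} W'` block-diagonal
#' across studies.  Finite for rank-deficient LD; for full-rank LD it differs
#' from [loglik_dense()] only by a configuration-independent Jacobian
#' constant (`0.5 log|Sigma|`), so posteriors agree across paths.  The
#' published variant of this transform (`I + m B Sigma_C B'` with
#' `B = Omega^{-1/2} W'`) is available via `lowrank_variant = "printed"` for
#' sensitivity checks.
#'
#' @inheritParams loglik_fast
#' @param truncation relative eigenvalue truncation threshold, see
#'   [eigen_ld()].
#' @param lowrank_variant `"exact"` (default) or `"printed"`.
#' @param m_factor for the printed variant, whether to keep the `m` (number
#'   of SNPs) scale factor.
#' @return log-likelihood (scalar).
#' @export
loglik_lowrank <- function(locus, config, tau_sq = 0.52, ncp_scale = 5.2,
                           truncation = 1e-8,
                           lowrank_variant = c("exact", "printed"),
                           m_factor = TRUE, cache = NULL) {
  J <- config_as_indices(config, locus$M)
  if (is.null(cache))
    cache <- locus_precompute(locus, "lowrank", truncation = truncation,
                              lowrank_variant = match.arg(lowrank_variant),
                              m_factor = m_factor)
  config_scan(cache, list(J), tau_sq, ncp_scale, locus$sample_sizes)
}

config_as_indices <- function(config, M) {
  config <- as.numeric(config)
  if (length(config) == M && all(config %in% c(0, 1))) {
    J <- which(config == 1)
  } else {
    J <- sort(unique(as.integer(config)))
    if (length(J) < 1L || any(J < 1L | J > M))
      stop("'config' must be a binary vector of length M or causal indices in 1..M")
  }
  if (length(J) < 1L) stop("configuration must have at least one causal SNP")
  J
}
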