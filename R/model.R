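#' Log prior probability of a causal configuration
#'
#' Each SNP is independently causal with probability `gamma`, so a binary
#' configuration `C` has prior `prod_j gamma^C_j (1-gamma)^(1-C_j)`,
#' returned on the log scale.
#'
#' @param config binary (0/1) vector of causal statuses, length M.
#' @param gamma per-SNP prior causal probability, in (0, 1).
#' @return log prior probability (scalar).
#' @export
config_prior_log <- function(config, gamma = 0.01) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0 || gamma >= 1)
    stop("'gamma' must be a single number in (0, 1)")
  config <- as_config(config)
  k <- sum(config)
  k * log(gamma) + (length(config) - k) * log1p(-gamma)
}

as_config <- function(config) {
  config <- as.numeric(config)
  if (length(config) < 1L || any(!config %in% c(0, 1)))
    stop("'config' must be a binary 0/1 vector")
  config
}

#' Enumerate causal configurations
#'
#' All binary configurations of M SNPs with between 1 and `max_causal` causal
#' entries, in nondecreasing causal count and, within each count,
#' lexicographic order of the causal index sets (so the first configuration
#' is always \{SNP 1\}).  The all-zero configuration is excluded; the model
#' is intended for loci with at least one causal signal.
#'
#' @param M number of SNPs.
#' @param max_causal maximum number of causal SNPs per configuration
#'   (K, with K <= M).
#' @return A list of integer vectors, each the sorted indices of the causal
#'   SNPs in one configuration; attribute `"M"` records the SNP count.
#' @export
enumerate_configs <- function(M, max_causal = 3L) {
  M <- as.integer(M); K <- as.integer(max_causal)
  if (M < 1L) stop("'M' must be >= 1")
  if (K < 1L || K > M) stop("'max_causal' must be in 1..M")
  out <- vector("list", sum(choose(M, seq_len(K))))
  pos <- 0L
  for (k in seq_len(K)) {
    cmb <- utils::combn(M, k)
    for (j in seq_len(ncol(cmb))) {
      pos <- pos + 1L
      out[[pos]] <- cmb[, j]
    }
  }
  attr(out, "M") <- M
  out
}

config_indices_to_binary <- function(idx, M) {
  v <- numeric(M); v[idx] <- 1; v
}

# Effective Q x Q study-covariance of a single causal SNP's non-centrality
# parameters: T[q,q] = tau^2 + sigma_q^2, T[q1,q2] = sqrt(N_q1 N_q2) sigma_g^2.
# With no sample sizes all studies share sigma^2 = ncp_scale^2 so
# T = tau^2 I + ncp_scale^2 * 1 1'.
study_covariance <- function(Q, tau_sq, ncp_scale, sample_sizes = NULL) {
  if (tau_sq < 0) stop("'tau_sq' must be >= 0")
  if (ncp_scale <= 0) stop("'ncp_scale' must be > 0")
  if (is.null(sample_sizes)) {
    s <- rep(ncp_scale, Q)
  } else {
    if (length(sample_sizes) != Q || any(sample_sizes <= 0))
      stop("'sample_sizes' must be ", Q, " positive numbers")
    # sigma_g^2 chosen so the smallest study has sd ncp_scale
    s <- ncp_scale * sqrt(sample_sizes / min(sample_sizes))
  }
  tau_sq * diag(Q) + outer(s, s)
}

#' Random-effects causal covariance matrix
#'
#' Builds the MQ x MQ covariance of the stacked per-study causal
#' non-centrality parameters for a given configuration, in study-major
#' layout (study 1's M SNPs first, then study 2's, ...).  For a causal SNP,
#' the within-study variance is `tau_sq + sigma_q^2` and the cross-study
#' covariance between studies q1 and q2 is `sqrt(N_q1 N_q2) * sigma_g^2`;
#' SNPs are independent of one another, and non-causal SNPs have zero
#' variance (or `epsilon` on the diagonal in the legacy full-rank mode).
#' With equal sample sizes this is the Kronecker product
#' `(tau_sq I_Q + sigma^2 1 1') %x% diag(causal indicator)`.
#'
#' @param config binary causal-status vector (length M) or integer vector of
#'   causal indices with attribute-free values in 1..M.
#' @param Q number of studies.
#' @param tau_sq between-study heterogeneity variance (>= 0).
#' @param ncp_scale standard deviation sigma of a causal SNP's mean
#'   non-centrality parameter in the smallest study (default 5.2, the
#'   genome-wide-significance Z-score).
#' @param sample_sizes optional per-study sample sizes; when given, study q's
#'   causal variance is `N_q / min(N) * ncp_scale^2`.
#' @param epsilon legacy ridge added to non-causal diagonal entries so the
#'   matrix is full rank (default 0; the low-rank likelihood path removes
#'   the need for it).
#' @return Symmetric PSD matrix of dimension `M * Q`.
#' @export
build_causal_covariance <- function(config, Q = 1L, tau_sq = 0.52,
                                    ncp_scale = 5.2, sample_sizes = NULL,
                                    epsilon = 0) {
  config <- as_config(config)
  if (epsilon < 0) stop("'epsilon' must be >= 0")
  M <- length(config)
  Tm <- study_covariance(Q, tau_sq, ncp_scale, sample_sizes)
  sig <- Tm %x% diag(config, nrow = M)
  if (epsilon > 0) {
    noncausal <- which(config == 0)
    for (q in seq_len(Q)) {
      jj <- (q - 1L) * M + noncausal
      sig[cbind(jj, jj)] <- epsilon
    }
  }
  sig
}
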