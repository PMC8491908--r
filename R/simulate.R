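# Synthetic multi-study loci for calibration studies.
#
# Two generation paths:
#  * direct    - model-faithful: causal mean NCPs lambda_m ~ |N(ncp_mean, 1)|,
#                per-study NCPs lambda_mq ~ N(lambda_m * sqrt(N_q/N_min),
#                tau^2), LD propagation Lambda_q = Sigma_q Lambda_Cq, and
#                Z-scores S_q ~ N(Lambda_q, Sigma_q).
#  * genotype  - individual-level: Gaussian-copula genotypes with target LD,
#                phenotype y = X beta + e with environmental variance scaled
#                to a target per-SNP heritability, per-SNP marginal
#                regression Z-scores, and in-sample LD.

#' AR(1) LD matrix
#'
#' Correlation matrix with entry `r^|i-j|`; positive definite for |r| < 1.
#'
#' @param M number of SNPs.
#' @param r lag-one correlation in (-1, 1).
#' @return M x M correlation matrix.
#' @export
ar1_ld <- function(M, r) {
  if (!is.numeric(r) || length(r) != 1L || abs(r) >= 1)
    stop("'r' must be in (-1, 1)")
  r^abs(outer(seq_len(M), seq_len(M), "-"))
}

#' Block compound-symmetry LD matrix
#'
#' Consecutive blocks of `block_size` SNPs with within-block correlation `r`
#' and zero correlation between blocks.
#'
#' @param M number of SNPs.
#' @param block_size SNPs per block (last block may be shorter).
#' @param r within-block correlation in (-1/(block_size-1), 1).
#' @return M x M correlation matrix.
#' @export
block_ld <- function(M, block_size, r) {
  if (!is.numeric(r) || length(r) != 1L || abs(r) >= 1)
    stop("'r' must be in (-1, 1)")
  blk <- rep(seq_len(ceiling(M / block_size)), each = block_size)[seq_len(M)]
  out <- (outer(blk, blk, "==")) * r
  diag(out) <- 1
  out
}

#' Simulate an LD matrix from a specification
#'
#' @param M number of SNPs.
#' @param spec list with `type` in `"identity"`, `"ar1"`, `"block"` and, as
#'   needed, `r` and `block_size`; or an M x M matrix passed through as-is.
#' @return M x M correlation matrix.
#' @export
sim_ld <- function(M, spec = list(type = "ar1", r = 0.9)) {
  if (is.matrix(spec)) return(validate_ld(spec, M, "sim_ld"))
  switch(match.arg(spec$type, c("identity", "ar1", "block")),
         identity = diag(M),
         ar1 = ar1_ld(M, spec$r),
         block = block_ld(M, if (is.null(spec$block_size)) 5L
                          else spec$block_size, spec$r))
}

#' Simulation design for synthetic loci
#'
#' Defaults mirror a desk-scale version of the calibration study the model
#' is meant for: two studies with distinct AR(1) LD (r = 0.9 and r = 0.5),
#' 50 SNPs, 1 or 2 shared causal SNPs, causal mean NCP 5.2 and heterogeneity
#' variance tau^2 = 0.52.
#'
#' @param n_studies number of studies Q.
#' @param n_snps number of SNPs M.
#' @param ld_spec list of Q LD specifications (see [sim_ld()]); recycled if
#'   length 1.
#' @param n_causal number of causal SNPs per locus, or a vector to sample
#'   from uniformly per replicate.
#' @param ncp_mean mean non-centrality parameter of a causal SNP in the
#'   smallest study (default 5.2).
#' @param tau_sq between-study heterogeneity variance (default 0.52).
#' @param sample_sizes optional per-study sample sizes (direct path: NCP
#'   means scale with sqrt(N_q / min N); genotype path: individuals
#'   simulated per study).
#' @param h2 per-causal-SNP heritability for the genotype path
#'   (default 0.005).
#' @param n_individuals individuals per study for the genotype path
#'   (default 2000).
#' @param maf minor allele frequency for the genotype path: a scalar, a
#'   length-2 range to draw from uniformly, or a length-M vector.
#' @return list of class `"sim_design"`.
#' @export
sim_design <- function(n_studies = 2L, n_snps = 50L,
                       ld_spec = list(list(type = "ar1", r = 0.9),
                                      list(type = "ar1", r = 0.5)),
                       n_causal = c(1L, 2L), ncp_mean = 5.2, tau_sq = 0.52,
                       sample_sizes = NULL, h2 = 0.005,
                       n_individuals = 2000L, maf = 0.3) {
  if (n_snps < 1L) stop("'n_snps' must be >= 1")
  if (any(n_causal < 1L) || any(n_causal > n_snps))
    stop("'n_causal' must be in 1..n_snps")
  if (tau_sq < 0) stop("'tau_sq' must be >= 0")
  if (any(h2 <= 0) || any(h2 >= 1)) stop("'h2' must be in (0, 1)")
  if (!is.list(ld_spec) || (is.list(ld_spec) && !is.null(ld_spec$type)))
    ld_spec <- list(ld_spec)
  if (length(ld_spec) == 1L) ld_spec <- rep(ld_spec, n_studies)
  if (length(ld_spec) > n_studies) ld_spec <- ld_spec[seq_len(n_studies)]
  if (length(ld_spec) != n_studies)
    stop("'ld_spec' must have 1 or ", n_studies, " elements")
  structure(list(n_studies = as.integer(n_studies),
                 n_snps = as.integer(n_snps), ld_spec = ld_spec,
                 n_causal = as.integer(n_causal), ncp_mean = ncp_mean,
                 tau_sq = tau_sq, sample_sizes = sample_sizes, h2 = h2,
                 n_individuals = as.integer(n_individuals), maf = maf),
            class = "sim_design")
}

# Draw causal SNPs uniformly, resampling until every causal pair is
# non-negatively correlated in every study (shared, positively correlated
# causal variants).
draw_truth <- function(M, c, ld_list, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    J <- sort(sample.int(M, c))
    if (c == 1L) return(J)
    ok <- all(vapply(ld_list, function(L) all(L[J, J] >= 0), TRUE))
    if (ok) return(J)
  }
  stop("could not draw ", c, " mutually positively-correlated causal SNPs")
}

# Symmetric PSD square root (eigenvalue clipping) -- used instead of chol so
# rank-deficient LD can be sampled from.
psd_sqrt <- function(V) {
  eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
  eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
}

#' Simulate one multi-study locus (direct, model-faithful path)
#'
#' Draws shared causal SNPs, a non-negative mean NCP per causal SNP
#' (`|N(ncp_mean, 1)|`), per-study NCPs around the (sample-size scaled) mean
#' with variance `tau_sq`, and per-study Z-scores from the induced
#' multivariate normal `S_q ~ N(Sigma_q Lambda_Cq, Sigma_q)`.
#'
#' @param design a [sim_design()].
#' @param seed integer seed (required; every replicate is reproducible).
#' @return list of class `"sim_replicate"` with `truth` (causal indices),
#'   `truth_config` (binary vector), `locus` ([multistudy_locus()]) and
#'   `provenance`.
#' @export
sim_locus <- function(design, seed) {
  stopifnot(inherits(design, "sim_design"))
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  M <- design$n_snps; Q <- design$n_studies
  ld <- lapply(design$ld_spec, function(sp) sim_ld(M, sp))
  c_n <- if (length(design$n_causal) > 1L)
    sample(design$n_causal, 1L) else design$n_causal
  J <- draw_truth(M, c_n, ld)
  ns <- design$sample_sizes
  scale_q <- if (is.null(ns)) rep(1, Q) else sqrt(ns / min(ns))
  lam <- abs(stats::rnorm(c_n, design$ncp_mean, 1))
  z <- vector("list", Q)
  roots <- lapply(ld, psd_sqrt)
  for (q in seq_len(Q)) {
    lam_q <- stats::rnorm(c_n, lam * scale_q[q], sqrt(design$tau_sq))
    lc <- numeric(M); lc[J] <- lam_q
    z[[q]] <- drop(ld[[q]] %*% lc + roots[[q]] %*% stats::rnorm(M))
  }
  truth <- numeric(M); truth[J] <- 1
  structure(list(
    truth = J, truth_config = truth,
    locus = multistudy_locus(z, ld, sample_sizes = ns),
    provenance = list(path = "direct-MVN", seed = seed, n_causal = c_n)),
    class = "sim_replicate")
}

# Standard bivariate normal rectangle probability P(Z1 < t1, Z2 < t2; rho)
# by 1-D quadrature over the conditional distribution.
pbinorm <- function(t1, t2, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(t1) * stats::pnorm(t2))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(z)
    stats::dnorm(z) * stats::pnorm((t2 - rho * z) / s),
    lower = -8, upper = t1, rel.tol = 1e-9)$value
}

# Latent (tetrachoric-style) correlation such that thresholding standard
# normals at qnorm(p1), qnorm(p2) yields Bernoulli indicators with Pearson
# correlation `target`.  The genotype (sum of two independent haplotypes)
# inherits this correlation.
latent_corr <- function(target, p1, p2) {
  if (abs(target) < 1e-10) return(0)
  t1 <- stats::qnorm(p1); t2 <- stats::qnorm(p2)
  den <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  g <- function(rho) (pbinorm(t1, t2, rho) - p1 * p2) / den - target
  lo <- -0.9999; hi <- 0.9999
  if (g(hi) < 0) return(hi)
  if (g(lo) > 0) return(lo)
  stats::uniroot(g, c(lo, hi), tol = 1e-7)$root
}

# Nearest-correlation repair by eigenvalue clipping.
fix_corr <- function(V, floor = 1e-8) {
  eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (min(eg$values) >= floor) return(V)
  W <- eg$vectors %*% (pmax(eg$values, floor) * t(eg$vectors))
  d <- sqrt(diag(W))
  W / outer(d, d)
}

#' Simulate one multi-study locus (genotype-phenotype path)
#'
#' Individual-level route: standardized genotypes with the target LD are
#' generated through a Gaussian copula (two latent haplotypes per individual,
#' thresholded at the minor allele frequency, with the latent correlation
#' calibrated so the realized genotype correlation matches the target), a
#' quantitative phenotype `y = X beta + e` is simulated with environmental
#' variance `var(X beta) * (1 / h2_total - 1)` so total heritability is
#' `n_causal * h2`, and per-SNP marginal regression yields Z-scores.  The
#' returned LD is the in-sample genotype correlation.
#'
#' @inheritParams sim_locus
#' @return list of class `"sim_replicate"` (see [sim_locus()]).
#' @export
sim_locus_genotype <- function(design, seed) {
  stopifnot(inherits(design, "sim_design"))
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  M <- design$n_snps; Q <- design$n_studies
  target_ld <- lapply(design$ld_spec, function(sp) sim_ld(M, sp))
  c_n <- if (length(design$n_causal) > 1L)
    sample(design$n_causal, 1L) else design$n_causal
  J <- draw_truth(M, c_n, target_ld)
  maf <- design$maf
  if (length(maf) == 2L && M != 2L) {
    maf <- stats::runif(M, min(maf), max(maf))
  } else if (length(maf) == 1L) maf <- rep(maf, M)
  if (length(maf) != M || any(maf < 0.01) || any(maf > 0.5))
    stop("'maf' must give per-SNP frequencies in [0.01, 0.5]")
  ns <- design$sample_sizes
  N_q <- if (is.null(ns)) rep(design$n_individuals, Q) else as.integer(ns)
  h_tot <- min(c_n * design$h2, 0.9)
  beta <- abs(stats::rnorm(c_n, 0, 1))          # shared across studies
  z <- vector("list", Q); ld <- vector("list", Q)
  for (q in seq_len(Q)) {
    # latent correlation calibrated per distinct (target r, maf pair) value
    lat <- diag(M)
    cache <- new.env(parent = emptyenv())
    for (i in seq_len(M - 1L)) for (j in seq((i + 1L), M)) {
      r <- target_ld[[q]][i, j]
      key <- paste(signif(r, 6), signif(maf[i], 6), signif(maf[j], 6))
      val <- cache[[key]]
      if (is.null(val)) {
        val <- latent_corr(r, maf[i], maf[j])
        cache[[key]] <- val
      }
      lat[i, j] <- lat[j, i] <- val
    }
    lat <- fix_corr(lat)
    rt <- psd_sqrt(lat)
    N <- N_q[q]
    thr <- stats::qnorm(maf)
    hap <- function() {
      Zl <- matrix(stats::rnorm(N * M), N, M) %*% rt
      sweep(Zl, 2L, thr, "<") + 0
    }
    G <- hap() + hap()
    X <- scale(G)
    bad <- which(is.nan(colSums(X)))            # monomorphic draws
    if (length(bad)) X[, bad] <- 0
    g_val <- drop(X[, J, drop = FALSE] %*% beta)
    var_g <- stats::var(g_val)
    e <- stats::rnorm(N, 0, sqrt(var_g * (1 / h_tot - 1)))
    y <- g_val + e
    r_my <- drop(stats::cor(X, y))
    r_my[is.na(r_my)] <- 0
    z[[q]] <- r_my * sqrt((N - 2) / pmax(1 - r_my^2, 1e-12))
    Cq <- stats::cor(G)
    Cq[is.na(Cq)] <- 0; diag(Cq) <- 1
    ld[[q]] <- (Cq + t(Cq)) / 2
  }
  truth <- numeric(M); truth[J] <- 1
  structure(list(
    truth = J, truth_config = truth,
    locus = multistudy_locus(z, ld, sample_sizes = ns),
    provenance = list(path = "genotype-regression", seed = seed,
                      n_causal = c_n, h2 = design$h2, beta = beta,
                      maf = maf)),
    class = "sim_replicate")
}

#' Calibration / evaluation harness
#'
#' Generates `n_reps` replicates from a design, runs a fine mapper on each,
#' and aggregates: sensitivity (fraction of replicates whose returned set
#' contains every true causal SNP), mean and median set size, and the mean
#' number of descending-PIP SNPs needed to cover the truth.
#'
#' @param design a [sim_design()].
#' @param n_reps number of replicates (>= 30 recommended).
#' @param fine_mapper function taking a [multistudy_locus()] and returning
#'   either a [finemap()] object or a character vector of set members.
#'   Defaults to [finemap()] with the design's `tau_sq` and `ncp_mean`.
#' @param seed integer seed; replicate r uses `seed + r`.
#' @param path `"direct"` (default) or `"genotype"` generation.
#' @return list with `sensitivity`, `mean_set_size`, `median_set_size`,
#'   `mean_rank_until_causal`, and a per-replicate data.frame `table`.
#' @export
evaluate_calibration <- function(design, n_reps = 100L, fine_mapper = NULL,
                                 seed = 1L, path = c("direct", "genotype")) {
  stopifnot(inherits(design, "sim_design"))
  path <- match.arg(path)
  gen <- if (path == "direct") sim_locus else sim_locus_genotype
  if (is.null(fine_mapper))
    fine_mapper <- function(locus)
      finemap(locus, tau_sq = design$tau_sq, ncp_scale = design$ncp_mean,
              warn_signs = FALSE)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rep_r <- gen(design, seed = seed + r)
    fit <- fine_mapper(rep_r$locus)
    if (inherits(fit, "finemap")) {
      set <- fit$set
      rank <- rank_until_causal(fit, rep_r$truth)
    } else {
      set <- as.character(fit)
      rank <- NA_integer_
    }
    truth_ids <- rep_r$locus$snp_ids[rep_r$truth]
    rows[[r]] <- data.frame(
      replicate = r, seed = seed + r, n_causal = length(rep_r$truth),
      set_size = length(set), captured = all(truth_ids %in% set),
      rank_until_causal = rank)
  }
  tab <- do.call(rbind, rows)
  list(sensitivity = mean(tab$captured),
       mean_set_size = mean(tab$set_size),
       median_set_size = stats::median(tab$set_size),
       mean_rank_until_causal = mean(tab$rank_until_causal),
       table = tab)
}
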