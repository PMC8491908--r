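test_that("dense likelihood: standard-normal base case and zero-mean symmetry", {
  loc <- multistudy_locus(0, matrix(1))
  expect_equal(loglik_dense(loc, matrix(0)), -0.5 * log(2 * pi))
  set.seed(21)
  M <- 6
  ld <- rand_corr(M)
  z <- rnorm(M, 0, 2)
  cc <- build_causal_covariance(rbinom(M, 1, 0.5), 1)
  a <- loglik_dense(multistudy_locus(z, ld), cc)
  b <- loglik_dense(multistudy_locus(-z, ld), cc)
  expect_equal(a, b)
})

test_that("dense likelihood agrees with an independently coded MVN density", {
  set.seed(22)
  for (i in 1:10) {
    M <- 5; Q <- 2
    rl <- rand_locus(M, Q, n_causal = sample(1:2, 1))
    J <- sort(sample.int(M, sample(1:3, 1)))
    cc <- build_causal_covariance(replace(rep(0, M), J, 1), Q)
    sig <- blockdiag_ld(rl$locus)
    expected <- dmvn_eigen(unlist(rl$locus$z), sig + sig %*% cc %*% sig)
    expect_equal(loglik_dense(rl$locus, cc), expected, tolerance = 1e-10)
  }
})

test_that("fast Woodbury path reproduces the dense oracle", {
  set.seed(23)
  for (i in 1:40) {
    M <- sample(3:20, 1); Q <- sample(1:3, 1)
    ns <- if (runif(1) < 0.5) NULL else sample(1000:9000, Q)
    rl <- rand_locus(M, Q, sample_sizes = ns)
    k <- sample(1:min(3, M), 1)
    J <- sort(sample.int(M, k))
    tau <- runif(1, 0, 1)
    cc <- build_causal_covariance(replace(rep(0, M), J, 1), Q, tau, 5.2, ns)
    d <- loglik_dense(rl$locus, cc)
    f <- loglik_fast(rl$locus, J, tau_sq = tau)
    expect_lt(abs(f - d) / (1 + abs(d)), 1e-8)
  }
  # degenerate K = M configuration
  set.seed(24)
  rl <- rand_locus(6, 2)
  cc <- build_causal_covariance(rep(1, 6), 2)
  expect_equal(loglik_fast(rl$locus, 1:6), loglik_dense(rl$locus, cc),
               tolerance = 1e-10)
})

test_that("no-LD single-causal likelihood matches the closed form", {
  set.seed(25)
  M <- 7; s2 <- 27.04
  z <- rnorm(M, 0, 2)
  loc <- multistudy_locus(z, diag(M))
  for (j in c(1L, 4L, 7L)) {
    closed <- -0.5 * (sum(z^2) - z[j]^2 * s2 / (1 + s2) + log(1 + s2) +
                        M * log(2 * pi))
    expect_equal(loglik_fast(loc, j, tau_sq = 0, ncp_scale = 5.2), closed,
                 tolerance = 1e-10)
  }
})

test_that("eigen_ld: spectra, truncation of perfect proxies, reconstruction", {
  eg <- eigen_ld(diag(4))
  expect_equal(eg$eigenvalues, rep(1, 4))
  expect_equal(eg$rank, 4L)
  # duplicated SNP pair (perfect LD) drops one component
  ld <- rand_corr(3)
  dup <- rbind(cbind(ld, ld[, 3]), c(ld[3, ], 1))   # SNP 4 == SNP 3
  eg2 <- eigen_ld(dup)
  expect_equal(eg2$rank, 3L)
  # reconstruction of a full-rank matrix from retained components
  set.seed(26)
  V <- rand_corr(6)
  eg3 <- eigen_ld(V)
  expect_lt(max(abs(eg3$eigenvectors %*% (eg3$eigenvalues *
                                            t(eg3$eigenvectors)) - V)), 1e-8)
  expect_error(eigen_ld(matrix(c(1, .5, .2, 1), 2)), "symmetric")
  # deterministic across repeated calls (sign convention applied)
  expect_identical(eigen_ld(V, z = rnorm(6))[1:4], eigen_ld(V, z = NULL))
})

test_that("low-rank path: posterior equivalence at full rank, finite at low rank", {
  set.seed(27)
  M <- 8; Q <- 2
  rl <- rand_locus(M, Q)
  fit_d <- finemap(rl$locus, path = "dense", max_causal = 2, warn_signs = FALSE)
  fit_l <- finemap(rl$locus, path = "lowrank", max_causal = 2, warn_signs = FALSE)
  fit_f <- finemap(rl$locus, path = "fast", max_causal = 2, warn_signs = FALSE)
  expect_equal(exp(fit_l$norm_log_post), exp(fit_d$norm_log_post),
               tolerance = 1e-6)
  expect_equal(exp(fit_f$norm_log_post), exp(fit_d$norm_log_post),
               tolerance = 1e-8)
  # rank-deficient LD: duplicated SNP; lowrank finite, dense refuses
  ld <- rand_corr(4)
  dup <- rbind(cbind(ld, ld[, 4]), c(ld[4, ], 1))
  z <- c(1, 0.5, -0.2, 4.8, 4.8)
  loc <- multistudy_locus(z, dup)
  expect_error(loglik_dense(loc, build_causal_covariance(c(0,0,0,1,0), 1)),
               "low-rank")
  expect_true(is.finite(loglik_lowrank(loc, 4)))
  fit <- finemap(loc, max_causal = 2, warn_signs = FALSE)
  expect_equal(unname(fit$pip[4]), unname(fit$pip[5]), tolerance = 1e-10)
})

test_that("identity LD: transformed statistics preserve the posterior", {
  set.seed(28)
  M <- 6
  z <- rnorm(M) + replace(numeric(M), 3, 5)
  loc <- multistudy_locus(z, diag(M))
  fit_l <- finemap(loc, path = "lowrank", max_causal = 2, warn_signs = FALSE)
  fit_d <- finemap(loc, path = "dense", max_causal = 2, warn_signs = FALSE)
  expect_equal(fit_l$pip, fit_d$pip, tolerance = 1e-8)
})

test_that("printed low-rank variant is available and the m switch acts", {
  set.seed(29)
  rl <- rand_locus(5, 2)
  a <- loglik_lowrank(rl$locus, 2, lowrank_variant = "printed", m_factor = TRUE)
  b <- loglik_lowrank(rl$locus, 2, lowrank_variant = "printed", m_factor = FALSE)
  d <- loglik_lowrank(rl$locus, 2)
  expect_true(is.finite(a) && is.finite(b))
  expect_false(isTRUE(all.equal(a, b)))
  expect_false(isTRUE(all.equal(a, d)))
})

test_that("per-locus caching gives bit-identical likelihoods", {
  set.seed(30)
  rl <- rand_locus(10, 2)
  cfgs <- enumerate_configs(10, 2)
  for (path in c("fast", "lowrank")) {
    cache <- refinemap:::locus_precompute(rl$locus, path)
    cached <- refinemap:::config_scan(cache, cfgs, 0.52, 5.2, NULL)
    fresh <- vapply(cfgs, function(J) {
      if (path == "fast") loglik_fast(rl$locus, J)
      else loglik_lowrank(rl$locus, J)
    }, 1.0)
    expect_identical(cached, fresh)
  }
})

test_that("likelihood ratio of the true single-SNP config grows with |Z_j|", {
  M <- 5
  loc_for <- function(zj) multistudy_locus(replace(rep(0.3, M), 3, zj), diag(M))
  lr <- vapply(c(2, 4, 6, 8), function(zj) {
    loc <- loc_for(zj)
    loglik_fast(loc, 3) - loglik_fast(loc, 1)
  }, 1.0)
  expect_true(all(diff(lr) > 0))
})
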