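test_that("posterior mass goes to the associated SNP; perfect proxies tie", {
  # two SNPs in zero LD, one strongly associated
  loc <- multistudy_locus(c(5.2, 0), diag(2))
  fit <- finemap(loc, max_causal = 1, warn_signs = FALSE)
  expect_gt(exp(fit$norm_log_post)[1], exp(fit$norm_log_post)[2])
  expect_identical(fit$set, "snp_1")
  # perfect LD, equal Z: exchangeable SNPs get identical PIPs
  ld <- matrix(c(1, 1, 1, 1), 2)
  loc2 <- multistudy_locus(c(4, 4), ld)
  fit2 <- finemap(loc2, max_causal = 2, warn_signs = FALSE)
  expect_equal(unname(fit2$pip[1]), unname(fit2$pip[2]), tolerance = 1e-10)
})

test_that("posteriors are normalized and PIPs sum to the expected causal count", {
  set.seed(41)
  for (i in 1:5) {
    rl <- rand_locus(sample(5:12, 1), sample(1:3, 1))
    fit <- finemap(rl$locus, max_causal = 3, warn_signs = FALSE)
    post <- exp(fit$norm_log_post)
    expect_equal(sum(post), 1, tolerance = 1e-10)
    expect_true(all(fit$pip >= 0 & fit$pip <= 1))
    expect_equal(sum(fit$pip), sum(fit$k * post), tolerance = 1e-10)
  }
})

test_that("PIPs match exhaustive brute-force summation over all configurations", {
  set.seed(42)
  M <- 6; Q <- 2
  rl <- rand_locus(M, Q, n_causal = 2)
  fit <- finemap(rl$locus, max_causal = M, warn_signs = FALSE)
  expect_length(fit$configs, 2^M - 1)
  bf <- brute_force_posterior(rl$locus)
  expect_equal(unname(fit$pip), bf$pip, tolerance = 1e-6)
  # with sample sizes too
  rl2 <- rand_locus(5, 2, sample_sizes = c(2000, 8000))
  fit2 <- finemap(rl2$locus, max_causal = 5, warn_signs = FALSE)
  bf2 <- brute_force_posterior(rl2$locus)
  expect_equal(unname(fit2$pip), bf2$pip, tolerance = 1e-6)
})

test_that("confidence set: exact compatible mass, monotone growth, nesting", {
  set.seed(43)
  rl <- rand_locus(8, 2)
  fit <- finemap(rl$locus, warn_signs = FALSE)
  expect_gte(fit$set_prob, fit$rho_star)
  expect_equal(refinemap:::compatible_mass(fit, fit$set_idx), fit$set_prob,
               tolerance = 1e-12)
  # adding any SNP never decreases compatible mass
  for (j in setdiff(seq_len(8), fit$set_idx)) {
    expect_gte(refinemap:::compatible_mass(fit, c(fit$set_idx, j)),
               fit$set_prob)
  }
  # nesting across confidence levels
  s50 <- confidence_set(fit, 0.5)$set_members
  s90 <- confidence_set(fit, 0.9)$set_members
  s99 <- confidence_set(fit, 0.99)$set_members
  expect_true(all(s50 %in% s90) && all(s90 %in% s99))
  # rho* = 1 with K = M captures every SNP with posterior support
  fitK <- finemap(rl$locus, max_causal = 8, rho_star = 1, warn_signs = FALSE)
  supported <- sort(unique(unlist(
    fitK$configs[exp(fitK$norm_log_post) > 0])))
  expect_true(all(fitK$snp_ids[supported] %in% fitK$set))
  expect_error(confidence_set(fit, 0), "rho_star")
  expect_error(confidence_set(fit, 1.1), "rho_star")
})

test_that("single-SNP locus and degenerate sets behave", {
  loc <- multistudy_locus(5, matrix(1))
  fit <- finemap(loc, max_causal = 1, warn_signs = FALSE)
  expect_identical(fit$set, "snp_1")
  expect_equal(fit$set_prob, 1)
})

test_that("greedy set is never smaller than the exhaustive minimum and rarely larger", {
  set.seed(44)
  n <- 40; same <- 0L
  for (i in seq_len(n)) {
    M <- sample(6:9, 1)
    rl <- rand_locus(M, sample(1:2, 1), n_causal = sample(1:2, 1))
    fit <- finemap(rl$locus, max_causal = 3, rho_star = 0.95,
                   warn_signs = FALSE)
    exact <- exhaustive_min_set_size(fit, 0.95)
    expect_gte(length(fit$set), exact)
    same <- same + (length(fit$set) == exact)
  }
  expect_gte(same / n, 0.9)
})

test_that("single study with tau^2 = 0 reduces to the single-study model", {
  set.seed(45)
  for (i in 1:8) {
    M <- sample(4:8, 1)
    rl <- rand_locus(M, 1, n_causal = 1)
    fit <- finemap(rl$locus, tau_sq = 0, max_causal = 3, warn_signs = FALSE)
    ref <- single_study_reference(rl$locus$z[[1]], rl$locus$ld[[1]],
                                  sigma = 5.2, max_causal = 3)
    expect_equal(unname(fit$pip), ref$pip, tolerance = 1e-8)
    expect_equal(exp(fit$norm_log_post), ref$post, tolerance = 1e-8)
  }
})

test_that("rank_until_causal counts descending-PIP SNPs until truth is covered", {
  set.seed(46)
  rl <- rand_locus(10, 2, n_causal = 1)
  fit <- finemap(rl$locus, warn_signs = FALSE)
  ord <- order(-fit$pip, seq_along(fit$pip))
  # truth equal to top SNP -> 1
  expect_equal(rank_until_causal(fit, ord[1]), 1L)
  # truth = ranks 1 and 3 -> 3
  expect_equal(rank_until_causal(fit, c(ord[1], ord[3])), 3L)
  # by id, and lower bound by count
  expect_gte(rank_until_causal(fit, fit$snp_ids[ord[c(2, 5)]]), 2L)
  expect_error(rank_until_causal(fit, "nope"), "unknown")
  expect_error(rank_until_causal(fit, integer(0)), "no causal")
})

test_that("null configuration can be included in the normalization", {
  loc <- multistudy_locus(c(0.1, -0.2, 0.05), diag(3))   # no signal
  fit0 <- finemap(loc, include_null = TRUE, warn_signs = FALSE)
  expect_length(fit0$configs, 3 + 3 + 1 + 1)
  expect_equal(sum(exp(fit0$norm_log_post)), 1, tolerance = 1e-10)
  # with no signal the null configuration should dominate
  expect_equal(which.max(fit0$norm_log_post), length(fit0$configs))
  fit1 <- finemap(loc, include_null = FALSE, warn_signs = FALSE)
  expect_length(fit1$configs, 7)
})

test_that("fit object methods print, summarize, and expose coefficients", {
  set.seed(47)
  rl <- rand_locus(6, 2)
  fit <- finemap(rl$locus, warn_signs = FALSE)
  expect_output(print(fit), "confidence set")
  s <- summary(fit)
  expect_s3_class(s, "summary.finemap")
  expect_output(print(s), "Expected number of causal")
  expect_identical(coef(fit), fit$pip)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
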