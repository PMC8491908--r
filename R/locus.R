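#' Construct a multi-study locus
#'
#' Bundles aligned per-study summary statistics for one genomic locus:
#' a signed Z-score vector and an LD (Pearson correlation) matrix per study,
#' with a single SNP ordering shared by every study.  All downstream
#' computation assumes this alignment; use [harmonize_studies()] to build a
#' locus from studies whose SNP lists only partially overlap.
#'
#' @param z list of Q numeric vectors of signed Z-scores, one per study,
#'   all of length M and in the same SNP order.  A single numeric vector is
#'   accepted for Q = 1.
#' @param ld list of Q symmetric M x M LD matrices (unit diagonal, entries in
#'   \[-1, 1\]), same order as `z`.  A single matrix is accepted for Q = 1.
#' @param snp_ids character vector of M SNP identifiers.  Defaults to
#'   `"snp_1" ... "snp_M"`.
#' @param sample_sizes optional numeric vector of Q per-study sample sizes
#'   (all > 0).  When present, per-study causal-effect variances are scaled
#'   by sample size (see [finemap()]).
#' @param labels optional character vector of Q study labels.
#'
#' @return An object of class `"multistudy_locus"`: a list with elements
#'   `snp_ids`, `z`, `ld`, `sample_sizes`, `labels`, `M`, `Q`.
#' @export
multistudy_locus <- function(z, ld, snp_ids = NULL, sample_sizes = NULL,
                             labels = NULL) {
  if (is.numeric(z)) z <- list(z)
  if (is.matrix(ld)) ld <- list(ld)
  if (!is.list(z) || !is.list(ld))
    stop("'z' and 'ld' must be lists (one element per study)")
  Q <- length(z)
  if (Q < 1L) stop("need at least one study")
  if (length(ld) != Q)
    stop("'z' has ", Q, " studies but 'ld' has ", length(ld))
  z <- lapply(z, function(v) as.numeric(v))
  M <- length(z[[1L]])
  if (M < 1L) stop("locus must contain at least one SNP")
  for (q in seq_len(Q)) {
    if (length(z[[q]]) != M)
      stop("study ", q, " has ", length(z[[q]]), " Z-scores; expected ", M)
    if (any(!is.finite(z[[q]])))
      stop("non-finite Z-score in study ", q)
    ld[[q]] <- validate_ld(as.matrix(ld[[q]]), M, paste0("study ", q))
  }
  if (is.null(snp_ids)) snp_ids <- paste0("snp_", seq_len(M))
  snp_ids <- as.character(snp_ids)
  if (length(snp_ids) != M) stop("'snp_ids' must have length ", M)
  if (anyDuplicated(snp_ids)) stop("duplicated SNP identifiers")
  if (!is.null(sample_sizes)) {
    sample_sizes <- as.numeric(sample_sizes)
    if (length(sample_sizes) != Q || any(!is.finite(sample_sizes)) ||
        any(sample_sizes <= 0))
      stop("'sample_sizes' must be ", Q, " positive numbers")
  }
  if (is.null(labels)) labels <- paste0("study_", seq_len(Q))
  structure(
    list(snp_ids = snp_ids, z = z, ld = ld, sample_sizes = sample_sizes,
         labels = as.character(labels), M = M, Q = Q),
    class = "multistudy_locus")
}

# Symmetry / range / diagonal checks shared by the constructor and the file
# reader.  Small asymmetries (< tol) are silently symmetrized.
validate_ld <- function(ld, M, where, tol = 1e-6) {
  if (!is.numeric(ld) || nrow(ld) != M || ncol(ld) != M)
    stop(where, ": LD matrix must be numeric ", M, " x ", M)
  if (any(!is.finite(ld))) stop(where, ": non-finite LD entry")
  asym <- max(abs(ld - t(ld)))
  if (asym > tol)
    stop(where, ": LD matrix asymmetric beyond tolerance (max |A - t(A)| = ",
         signif(asym, 3), ")")
  ld <- (ld + t(ld)) / 2
  if (max(abs(ld)) > 1 + tol)
    stop(where, ": LD entries must lie in [-1, 1]")
  dmax <- max(abs(diag(ld) - 1))
  if (dmax > tol)
    stop(where, ": LD diagonal must be 1 (max deviation ", signif(dmax, 3), ")")
  diag(ld) <- 1
  ld[ld > 1] <- 1
  ld[ld < -1] <- -1
  dimnames(ld) <- NULL
  ld
}

#' @export
print.multistudy_locus <- function(x, ...) {
  cat("Multi-study locus: ", x$M, " SNPs x ", x$Q, " studies\n", sep = "")
  for (q in seq_len(x$Q)) {
    cat(sprintf("  %s: max |Z| = %.2f%s\n", x$labels[q], max(abs(x$z[[q]])),
                if (!is.null(x$sample_sizes))
                  sprintf(", N = %g", x$sample_sizes[q]) else ""))
  }
  invisible(x)
}

#' Intersect and align studies on shared SNPs
#'
#' Restricts every study to the SNPs present in all of them and reorders
#' Z-scores and LD matrices to a common order (the order in which the shared
#' SNPs appear in the first study).  Dropped SNPs are reported via `message()`.
#'
#' @param studies list of per-study records as returned by [read_study()]:
#'   each a list with `snp_ids`, `z`, `ld`, and optionally `sample_size`,
#'   `label`.
#' @return A [multistudy_locus()].
#' @export
harmonize_studies <- function(studies) {
  if (!is.list(studies) || length(studies) < 1L)
    stop("'studies' must be a non-empty list")
  ids <- lapply(studies, function(s) as.character(s$snp_ids))
  common <- Reduce(intersect, ids)
  if (length(common) == 0L)
    stop("no SNPs shared by all studies (per-study counts: ",
         paste(vapply(ids, length, 1L), collapse = ", "), ")")
  # keep the first study's ordering of the shared SNPs
  common <- ids[[1L]][ids[[1L]] %in% common]
  if (length(common) < 2L)
    stop("fewer than 2 SNPs shared by all studies")
  dropped <- unique(unlist(lapply(ids, setdiff, y = common)))
  if (length(dropped))
    message("harmonize_studies: dropped ", length(dropped),
            " SNP(s) absent from some study: ",
            paste(utils::head(dropped, 10L), collapse = ", "),
            if (length(dropped) > 10L) ", ..." else "")
  z <- vector("list", length(studies))
  ld <- vector("list", length(studies))
  ns <- vapply(studies, function(s) {
    if (is.null(s$sample_size)) NA_real_ else as.numeric(s$sample_size)
  }, 1.0)
  labels <- vapply(seq_along(studies), function(q) {
    if (is.null(studies[[q]]$label)) paste0("study_", q)
    else as.character(studies[[q]]$label)
  }, "")
  for (q in seq_along(studies)) {
    idx <- match(common, ids[[q]])
    z[[q]] <- as.numeric(studies[[q]]$z)[idx]
    ld[[q]] <- as.matrix(studies[[q]]$ld)[idx, idx, drop = FALSE]
  }
  multistudy_locus(z = z, ld = ld, snp_ids = common,
                   sample_sizes = if (all(is.na(ns))) NULL else ns,
                   labels = labels)
}

# Heuristic allele-harmonization warning: many SNP pairs in strong positive LD
# but with opposite-sign Z-scores suggests the Z files were not signed to a
# common effect allele.  Alleles themselves are the user's responsibility
# (the Z/LD file formats carry no allele columns).
check_sign_consistency <- function(locus, ld_min = 0.9, frac_warn = 0.1) {
  n_bad <- 0L; n_tot <- 0L
  for (q in seq_len(locus$Q)) {
    strong <- which(locus$ld[[q]] > ld_min & upper.tri(locus$ld[[q]]),
                    arr.ind = TRUE)
    if (nrow(strong) == 0L) next
    zq <- locus$z[[q]]
    opp <- zq[strong[, 1L]] * zq[strong[, 2L]] < 0 &
      pmin(abs(zq[strong[, 1L]]), abs(zq[strong[, 2L]])) > 2
    n_bad <- n_bad + sum(opp)
    n_tot <- n_tot + nrow(strong)
  }
  if (n_tot > 0L && n_bad / n_tot > frac_warn)
    warning(sprintf(paste0(
      "%d of %d SNP pairs with LD > %.2f have opposite-sign Z-scores; ",
      "check that Z-scores are signed to a common effect allele"),
      n_bad, n_tot, ld_min), call. = FALSE)
  invisible(n_bad)
}
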