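# Plain-text file interfaces.
#
# Z-score file: two whitespace-separated columns (SNP id, signed Z), header
# optional and auto-detected (non-numeric second field).  LD file: an M x M
# whitespace-separated numeric matrix.  Scientific notation accepted.

#' Read one study's Z-score and LD files
#'
#' @param z_path path to the Z-score file.
#' @param ld_path path to the LD matrix file.
#' @param sample_size optional study sample size.
#' @param label optional study label (defaults to the Z file name).
#' @return list with `snp_ids`, `z`, `ld`, `sample_size`, `label`, ready for
#'   [harmonize_studies()].
#' @export
read_study <- function(z_path, ld_path, sample_size = NULL, label = NULL) {
  if (!file.exists(z_path)) stop("Z-score file not found: ", z_path)
  if (!file.exists(ld_path)) stop("LD file not found: ", ld_path)
  first <- strsplit(trimws(readLines(z_path, n = 1L)), "[ \t]+")[[1L]]
  header <- length(first) >= 2L && is.na(suppressWarnings(as.numeric(first[2L])))
  ztab <- utils::read.table(z_path, header = header,
                            colClasses = c("character", "numeric"),
                            col.names = c("snp", "z"))
  if (ncol(ztab) < 2L)
    stop(z_path, ": expected two columns (SNP id, Z-score)")
  if (any(!is.finite(ztab$z)))
    stop(z_path, ": non-finite Z-score at line ",
         which(!is.finite(ztab$z))[1L] + header)
  ld <- tryCatch(as.matrix(utils::read.table(ld_path, header = FALSE)),
                 error = function(e) stop(ld_path, ": ", conditionMessage(e)))
  storage.mode(ld) <- "numeric"
  if (any(!is.finite(ld))) {
    bad <- which(!is.finite(ld), arr.ind = TRUE)[1L, ]
    stop(ld_path, ": non-numeric entry at line ", bad[1L],
         ", column ", bad[2L])
  }
  M <- nrow(ztab)
  if (nrow(ld) != M || ncol(ld) != M)
    stop("dimension mismatch: ", z_path, " has ", M, " SNPs but ", ld_path,
         " is ", nrow(ld), " x ", ncol(ld))
  ld <- validate_ld(ld, M, ld_path)
  list(snp_ids = ztab$snp, z = ztab$z, ld = ld,
       sample_size = sample_size,
       label = if (is.null(label)) basename(z_path) else label)
}

#' Read and harmonize a multi-study locus from files
#'
#' @param z_paths character vector of Z-score file paths, one per study.
#' @param ld_paths character vector of LD file paths, same order.
#' @param sample_sizes optional per-study sample sizes.
#' @param labels optional study labels.
#' @return A [multistudy_locus()].
#' @export
read_locus <- function(z_paths, ld_paths, sample_sizes = NULL,
                       labels = NULL) {
  Q <- length(z_paths)
  if (length(ld_paths) != Q)
    stop("need one LD file per Z file (", Q, " Z files, ",
         length(ld_paths), " LD files)")
  studies <- lapply(seq_len(Q), function(q)
    read_study(z_paths[q], ld_paths[q],
               sample_size = if (is.null(sample_sizes)) NULL
                             else sample_sizes[q],
               label = if (is.null(labels)) NULL else labels[q]))
  harmonize_studies(studies)
}

#' Write fine-mapping results to files
#'
#' Writes `<prefix>_set.txt` (the confidence set, one SNP id per line in
#' descending-PIP order), `<prefix>_post.txt` (tab-separated table: SNP id,
#' PIP, in-set flag) and `<prefix>_summary.json` (run metadata and headline
#' numbers).
#'
#' @param fit a [finemap()] object.
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
write_results <- function(fit, prefix) {
  stopifnot(inherits(fit, "finemap"))
  paths <- paste0(prefix, c("_set.txt", "_post.txt", "_summary.json"))
  writeLines(fit$set, paths[1L])
  ord <- pip_order(fit$pip)
  tab <- data.frame(snp = fit$snp_ids[ord],
                    pip = sprintf("%.10g", unname(fit$pip[ord])),
                    in_set = as.integer(fit$snp_ids[ord] %in% fit$set))
  utils::write.table(tab, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summ <- list(
    n_snps = fit$M, n_studies = fit$Q, max_causal = fit$params$max_causal,
    rho_star = fit$rho_star, tau_sq = fit$params$tau_sq,
    ncp_scale = fit$params$ncp_scale, gamma = fit$params$gamma,
    path = fit$params$path, set_size = length(fit$set),
    set_prob = fit$set_prob, runtime_sec = fit$runtime,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("refinemap")))
  jsonlite::write_json(summ, paths[3L], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Write a simulated replicate in the package's file formats
#'
#' Emits, per study, `<prefix>_study<q>.z` and `<prefix>_study<q>.ld`, plus
#' a tab-separated truth sidecar `<prefix>_truth.txt` (SNP id, causal flag),
#' so simulated loci can be round-tripped through [read_locus()] and the
#' command-line interface.
#'
#' @param rep a `"sim_replicate"` from [sim_locus()] or
#'   [sim_locus_genotype()].
#' @param prefix output path prefix.
#' @return invisibly, the written file paths.
#' @export
write_replicate <- function(rep, prefix) {
  stopifnot(inherits(rep, "sim_replicate"))
  locus <- rep$locus
  paths <- character(0)
  for (q in seq_len(locus$Q)) {
    zp <- sprintf("%s_study%d.z", prefix, q)
    lp <- sprintf("%s_study%d.ld", prefix, q)
    utils::write.table(
      data.frame(snp = locus$snp_ids, z = sprintf("%.10g", locus$z[[q]])),
      zp, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(format(locus$ld[[q]], digits = 10, scientific = TRUE,
                              trim = TRUE),
                       lp, sep = " ", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    paths <- c(paths, zp, lp)
  }
  tp <- paste0(prefix, "_truth.txt")
  utils::write.table(data.frame(snp = locus$snp_ids,
                                causal = as.integer(rep$truth_config)),
                     tp, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(paths, tp))
}
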