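#' Filter genes with low counts
#'
#' Retains genes whose raw-library CPM (count / library size * 1e6, before
#' any between-sample normalization) is at least `min_cpm` in at least
#' `min_samples` samples.  The default `min_samples` is the smallest
#' condition group size, the common convention for keeping genes
#' expressed in at least one full group.
#'
#' @param m A [count_matrix()].
#' @param min_cpm Raw CPM threshold (0 retains everything).
#' @param min_samples Minimum number of samples at or above `min_cpm`;
#'   default: smallest group size.
#' @return A [count_matrix()] with the retained genes; warns (does not
#'   error) if no gene survives.
#' @export
filter_low_counts <- function(m, min_cpm = 1, min_samples = NULL) {
  stopifnot(inherits(m, "count_matrix"), min_cpm >= 0)
  if (is.null(min_samples))
    min_samples <- min(table(m$condition_of))
  if (min_samples < 1 || min_samples > ncol(m$counts))
    stop("min_samples must lie in [1, number of samples]")
  lib <- colSums(m$counts)
  cpm_raw <- sweep(m$counts, 2, lib, "/") * 1e6
  keep <- rowSums(cpm_raw >= min_cpm) >= min_samples
  if (!any(keep)) warning("no genes pass the count filter")
  count_matrix(m$counts[keep, , drop = FALSE], m$condition_of,
               replicate = m$replicate)
}

#' Upper-quartile CPM normalization
#'
#' Per sample, the scaling factor is the 75th percentile (linear
#' interpolation, `stats::quantile` type 7) of that sample's *nonzero*
#' gene counts divided by its library size.  Factors are rescaled to unit
#' geometric mean; the effective library is library size times the
#' rescaled factor, and CPM = count / effective library * 1e6.
#'
#' @param m A [count_matrix()].
#' @return A `normalized_expression` object: list with `cpm` (matrix),
#'   `uq_factors` (rescaled, unit geometric mean), `lib_sizes`, and
#'   `condition_of`.
#' @export
upper_quartile_normalize <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  lib <- colSums(m$counts)
  zero <- colnames(m$counts)[lib == 0 | colSums(m$counts > 0) == 0]
  if (length(zero))
    stop("all-zero sample(s): ", paste(zero, collapse = ", "))
  f <- vapply(seq_len(ncol(m$counts)), function(j) {
    x <- m$counts[, j]
    stats::quantile(x[x > 0], 0.75, names = FALSE, type = 7) / lib[j]
  }, numeric(1))
  f_tilde <- f / exp(mean(log(f)))
  eff_lib <- lib * f_tilde
  cpm <- sweep(m$counts, 2, eff_lib, "/") * 1e6
  structure(list(cpm = cpm,
                 uq_factors = stats::setNames(f_tilde, colnames(m$counts)),
                 lib_sizes = lib,
                 condition_of = m$condition_of),
            class = "normalized_expression")
}

#' @export
print.normalized_expression <- function(x, ...) {
  cat("normalized_expression:", nrow(x$cpm), "genes x", ncol(x$cpm),
      "samples (upper-quartile CPM)\n")
  invisible(x)
}

#' Per-gene log2 fold change between two conditions
#'
#' log2((mean test CPM + pseudocount) / (mean ref CPM + pseudocount)), with
#' the differential-expression call at `|log2FC| >= tau_de` (boundary
#' inclusive, matching thresholds printed as <= -2 or >= 2).
#'
#' @param e A `normalized_expression` from [upper_quartile_normalize()].
#' @param ref,test Condition labels (test vs ref).
#' @param pseudocount Offset on the CPM scale, > 0, keeps log2FC finite.
#' @param tau_de DE threshold on |log2FC|.
#' @return A `de_results` data.frame: gene_id, mean_cpm_ref, mean_cpm_test,
#'   log2fc, passes_de.
#' @export
log2_fold_change <- function(e, ref, test, pseudocount = 1, tau_de = 2) {
  stopifnot(inherits(e, "normalized_expression"), pseudocount > 0)
  for (cond in c(ref, test))
    if (!any(e$condition_of == cond))
      stop("condition with zero samples: ", cond)
  mean_ref <- rowMeans(e$cpm[, e$condition_of == ref, drop = FALSE])
  mean_test <- rowMeans(e$cpm[, e$condition_of == test, drop = FALSE])
  lfc <- log2((mean_test + pseudocount) / (mean_ref + pseudocount))
  out <- data.frame(gene_id = rownames(e$cpm),
                    mean_cpm_ref = unname(mean_ref),
                    mean_cpm_test = unname(mean_test),
                    log2fc = unname(lfc),
                    passes_de = abs(unname(lfc)) >= tau_de,
                    stringsAsFactors = FALSE)
  attr(out, "tau_de") <- tau_de
  attr(out, "comparison") <- paste0(test, "_vs_", ref)
  class(out) <- c("de_results", "data.frame")
  out
}

.as_ranked_list <- function(tab) {
  if (anyDuplicated(tab$gene)) stop("duplicated gene ids in ranked list")
  ord <- order(-tab$metric, tab$gene, method = "radix")
  out <- data.frame(gene = tab$gene[ord], metric = tab$metric[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Build a ranked gene list from fold-change results
#'
#' All genes (not only DE-passing ones) sorted by log2 fold change
#' descending; exact metric ties are broken by lexicographic gene id
#' (C locale), so the ordering is reproducible.
#'
#' @param d A `de_results` data.frame from [log2_fold_change()].
#' @return A `ranked_list` data.frame with columns `gene`, `metric`.
#' @export
build_rank_list <- function(d) {
  .as_ranked_list(data.frame(gene = d$gene_id, metric = d$log2fc,
                             stringsAsFactors = FALSE))
}

#' Write differential-expression results as TSV
#'
#' @param d A `de_results` data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_de_results <- function(d, path) .write_tsv(as.data.frame(d), path)
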