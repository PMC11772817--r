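# qRT-PCR relative expression.  Two conventions are provided because the
# field's standard delta-Ct rule, 2^-(CT_gene - CT_housekeeping), and the
# literal form sometimes printed in methods sections,
# 2^-(CT_housekeeping - CT_gene), are exact reciprocals: the printed form
# makes expression *increase* with the target's CT.  The default is the
# standard rule; "as_printed" preserves the literal formula.  No intent is
# guessed — pick the convention explicitly when it matters.

.ct_of <- function(t, gene, sample) {
  v <- t$ct$ct[t$ct$gene == gene & t$ct$sample == sample]
  if (!length(v))
    stop("missing CT for (", gene, ", ", sample, ")")
  mean(v)
}

#' Relative expression from CT values
#'
#' The housekeeping CT is the arithmetic mean over the table's
#' housekeeping genes (equivalently, geometric-mean aggregation on the
#' expression scale).  Convention `"standard"` computes
#' 2^-(CT_gene - CT_HK); `"as_printed"` computes 2^-(CT_HK - CT_gene),
#' its exact reciprocal.
#'
#' @param t A [ct_table()].
#' @param gene Gene of interest.
#' @param sample Sample id.
#' @param convention `"standard"` (default) or `"as_printed"`.
#' @return Positive scalar.
#' @export
relative_expression <- function(t, gene, sample,
                                convention = c("standard", "as_printed")) {
  stopifnot(inherits(t, "ct_table"))
  convention <- match.arg(convention)
  ct_gene <- .ct_of(t, gene, sample)
  ct_hk <- mean(vapply(t$housekeeping_genes, .ct_of, numeric(1),
                       t = t, sample = sample))
  d <- ct_gene - ct_hk
  if (convention == "standard") 2^(-d) else 2^d
}

#' Fold change of a gene between two conditions
#'
#' Geometric mean of per-sample relative expressions in the test condition
#' divided by the geometric mean in the control condition (expressions are
#' ratio-scale, so the geometric mean is the appropriate cross-sample
#' summary).  Switching convention maps the result to its reciprocal.
#'
#' @param t A [ct_table()].
#' @param gene Gene of interest.
#' @param test_condition,control_condition Condition labels.
#' @param convention See [relative_expression()].
#' @return Positive scalar fold change.
#' @export
fold_change_vs_control <- function(t, gene, test_condition,
                                   control_condition,
                                   convention = c("standard", "as_printed")) {
  stopifnot(inherits(t, "ct_table"))
  convention <- match.arg(convention)
  geo <- function(cond) {
    smp <- names(t$condition_of)[t$condition_of == cond]
    smp <- intersect(smp, unique(t$ct$sample))
    if (!length(smp)) stop("condition with zero samples: ", cond)
    vals <- vapply(smp, function(s)
      relative_expression(t, gene, s, convention), numeric(1))
    exp(mean(log(vals)))
  }
  geo(test_condition) / geo(control_condition)
}

#' Fold changes of all assayed genes between two conditions
#'
#' @inheritParams fold_change_vs_control
#' @param genes Genes to report; default all non-housekeeping genes.
#' @return data.frame: gene, fold_change, log2fc.
#' @export
qpcr_fold_changes <- function(t, test_condition, control_condition,
                              genes = NULL,
                              convention = c("standard", "as_printed")) {
  convention <- match.arg(convention)
  if (is.null(genes))
    genes <- sort(setdiff(unique(t$ct$gene), t$housekeeping_genes))
  fc <- vapply(genes, fold_change_vs_control, numeric(1), t = t,
               test_condition = test_condition,
               control_condition = control_condition,
               convention = convention)
  data.frame(gene = genes, fold_change = unname(fc),
             log2fc = log2(unname(fc)), stringsAsFactors = FALSE)
}
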