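#' Secretome membership lookup
#'
#' Closed-world lookup against the database's extracellular-region list:
#' genes absent from the database are reported `FALSE`.
#'
#' @param genes Character vector of gene ids.
#' @param db An [annotation_db()].
#' @return Named logical vector.
#' @export
annotate_secretome <- function(genes, db) {
  stopifnot(inherits(db, "annotation_db"))
  stats::setNames(genes %in% db$secretome, genes)
}

#' Query IFN-regulation evidence for one gene
#'
#' Aggregates all interferome records for the gene whose fold change meets
#' the threshold (default 1.5).  A gene is IFN-regulated iff at least one
#' record passes.
#'
#' @param gene Gene id.
#' @param db An [annotation_db()].
#' @param tau_ifn Fold-change threshold, > 0.
#' @return List: `gene`, `is_ifn_regulated`, `types` (subset of I/II/III),
#'   `directions` (named by type, "up"/"down"/"both"), `records` (the
#'   passing rows).
#' @export
query_interferome <- function(gene, db, tau_ifn = 1.5) {
  stopifnot(inherits(db, "annotation_db"), tau_ifn > 0)
  rec <- db$interferome[db$interferome$gene == gene &
                        db$interferome$fold_change >= tau_ifn, , drop = FALSE]
  types <- sort(unique(rec$ifn_type))
  directions <- vapply(types, function(tt) {
    d <- unique(rec$direction[rec$ifn_type == tt])
    if (length(d) > 1) "both" else d
  }, character(1))
  list(gene = gene, is_ifn_regulated = nrow(rec) > 0,
       types = types, directions = directions, records = rec)
}

#' Vectorized IFN-regulation membership
#'
#' @param genes Character vector.
#' @param db An [annotation_db()].
#' @param tau_ifn Fold-change threshold.
#' @param type Optional IFN type filter ("I", "II", "III").
#' @param direction Optional direction filter ("up"/"down").
#' @return Named logical vector.
#' @export
is_ifn_regulated <- function(genes, db, tau_ifn = 1.5,
                             type = NULL, direction = NULL) {
  stopifnot(inherits(db, "annotation_db"), tau_ifn > 0)
  rec <- db$interferome[db$interferome$fold_change >= tau_ifn, , drop = FALSE]
  if (!is.null(type)) rec <- rec[rec$ifn_type %in% type, , drop = FALSE]
  if (!is.null(direction))
    rec <- rec[rec$direction %in% direction, , drop = FALSE]
  stats::setNames(genes %in% rec$gene, genes)
}

#' Summarize IFN regulation among differentially expressed genes
#'
#' Computes, for the up- and down-regulated DE genes separately, the
#' fraction that are IFN-regulated, and the per-type composition of all
#' IFN-regulated DE genes under two counting modes: `any` (a gene counts
#' toward every type it is annotated with) and `exclusive` (a gene counts
#' only if annotated with exactly one type).  Genes carrying both up and
#' down records at threshold count toward the direction matching their DE
#' direction.
#'
#' @param de A `de_results` data.frame from [log2_fold_change()].
#' @param db An [annotation_db()].
#' @param tau_ifn Fold-change threshold.
#' @return List: `up_fraction`, `down_fraction` (NA when a direction has
#'   no DE genes), `n_up_de`, `n_down_de`, `type_share_any`,
#'   `type_share_exclusive` (named numeric over I/II/III), `mode` notes.
#' @export
summarize_ifn_regulation <- function(de, db, tau_ifn = 1.5) {
  stopifnot(nrow(de) > 0)
  up <- de$gene_id[de$passes_de & de$log2fc > 0]
  down <- de$gene_id[de$passes_de & de$log2fc < 0]
  ifn_frac <- function(genes, dir) {
    if (!length(genes)) return(NA_real_)
    mean(is_ifn_regulated(genes, db, tau_ifn, direction = dir))
  }
  # direction-matched counting: up-DE genes against "up" records, etc.
  up_fraction <- ifn_frac(up, "up")
  down_fraction <- ifn_frac(down, "down")
  de_genes <- c(up, down)
  reg <- de_genes[is_ifn_regulated(de_genes, db, tau_ifn)]
  share <- function(mode) {
    counts <- stats::setNames(numeric(3), c("I", "II", "III"))
    if (!length(reg)) return(counts)
    for (g in reg) {
      tys <- query_interferome(g, db, tau_ifn)$types
      if (mode == "exclusive" && length(tys) != 1) next
      counts[tys] <- counts[tys] + 1
    }
    counts / length(reg)
  }
  list(up_fraction = up_fraction, down_fraction = down_fraction,
       n_up_de = length(up), n_down_de = length(down),
       n_ifn_regulated = length(reg),
       type_share_any = share("any"),
       type_share_exclusive = share("exclusive"))
}
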