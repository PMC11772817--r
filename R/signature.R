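# Multi-assay evidence integration: the pipeline's core computation.
# Evidence records are (gene, assay, comparison, direction, magnitude,
# significant) rows; the derivation rule is a pure set-logical conjunction
# over them, with each conjunct individually toggleable.

.ASSAY_MODALITY <- c(rnaseq = "transcriptomic", qrtpcr = "transcriptomic",
                     array = "proteomic", elisa = "proteomic",
                     western = "proteomic")
.COMPARISONS <- c("PTR_vs_P", "KD_vs_PTR")

#' Construct an evidence matrix from raw records
#'
#' @param records data.frame with columns `gene`, `assay` (rnaseq, qrtpcr,
#'   array, elisa, western), `comparison` (PTR_vs_P, KD_vs_PTR),
#'   `direction` (up/down/unchanged), `magnitude` (log2 scale where
#'   applicable), `significant` (logical).  Modality is derived from the
#'   assay; "unchanged" records are forced non-significant.  At most one
#'   record per (gene, assay, comparison).
#' @return An `evidence_matrix` data.frame (adds a `modality` column).
#' @export
evidence_matrix <- function(records) {
  need <- c("gene", "assay", "comparison", "direction", "magnitude",
            "significant")
  if (!all(need %in% names(records)))
    stop("evidence records need columns: ", paste(need, collapse = ", "))
  bad <- setdiff(records$assay, names(.ASSAY_MODALITY))
  if (length(bad)) stop("unknown assay(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(records$comparison, .COMPARISONS)
  if (length(bad))
    stop("unknown comparison(s): ", paste(bad, collapse = ", "))
  if (any(!records$direction %in% c("up", "down", "unchanged")))
    stop("direction must be up/down/unchanged")
  key <- paste(records$gene, records$assay, records$comparison)
  if (anyDuplicated(key))
    stop("duplicate evidence for (gene, assay, comparison): ",
         key[duplicated(key)][1])
  records$significant <- records$significant &
    records$direction != "unchanged"
  records$modality <- unname(.ASSAY_MODALITY[records$assay])
  records <- records[order(records$gene, records$assay,
                           records$comparison), , drop = FALSE]
  rownames(records) <- NULL
  class(records) <- c("evidence_matrix", "data.frame")
  records
}

#' @export
print.evidence_matrix <- function(x, ...) {
  cat("evidence_matrix:", nrow(x), "records,",
      length(unique(x$gene)), "genes, assays:",
      paste(sort(unique(x$assay)), collapse = ", "), "\n")
  invisible(x)
}

#' Preliminary candidate list: secretory, IFN-regulated, transcript-DE
#'
#' Genes passing the DE call in the requested direction (log2FC >= +tau_de
#' for "up"; <= -tau_de for "down") that are secretome members and
#' IFN-regulated at `tau_ifn`.
#'
#' @param de A `de_results` data.frame from [log2_fold_change()].
#' @param db An [annotation_db()].
#' @param tau_de DE threshold on |log2FC|.
#' @param tau_ifn Interferome fold-change threshold.
#' @param direction "up" (default) or "down" for the mirrored variant.
#' @return Sorted character vector of candidate gene ids (may be empty).
#' @export
build_preliminary_list <- function(de, db, tau_de = 2, tau_ifn = 1.5,
                                   direction = c("up", "down")) {
  direction <- match.arg(direction)
  lfc_ok <- if (direction == "up") de$log2fc >= tau_de
            else de$log2fc <= -tau_de
  cand <- de$gene_id[de$passes_de & lfc_ok]
  cand <- cand[annotate_secretome(cand, db)]
  cand <- cand[is_ifn_regulated(cand, db, tau_ifn)]
  sort(cand)
}

# direction and significance from a log2 magnitude and an effect floor
.call_direction <- function(log2_mag, floor) {
  ifelse(abs(log2_mag) < floor, "unchanged",
         ifelse(log2_mag > 0, "up", "down"))
}

#' Assemble an evidence matrix from stage outputs
#'
#' Collates RNA-seq DE tables, cytokine-array fold changes, and qRT-PCR
#' fold changes (each a named list keyed by comparison, `PTR_vs_P` and/or
#' `KD_vs_PTR`) into one [evidence_matrix()].  Array targets are mapped to
#' gene ids through an explicit two-column map (`target`, `gene`); no
#' fuzzy matching is attempted, and unmapped targets are skipped with a
#' warning.  For assays run without replicates (the array) and for qPCR
#' ratios, "significant" means |log2 magnitude| at or above
#' `effect_floor` (default 0.58, about 1.5-fold); RNA-seq records inherit
#' their `passes_de` call.
#'
#' @param de Named list of `de_results` by comparison.
#' @param array_fc Named list of [array_fold_changes()] tables by
#'   comparison.
#' @param qpcr_fc Named list of [qpcr_fold_changes()] tables by
#'   comparison.
#' @param extra Optional data.frame of pre-formed evidence records (e.g.
#'   ELISA or western calls) with [evidence_matrix()] columns.
#' @param target_map data.frame (`target`, `gene`) mapping array protein
#'   targets to gene ids; required when `array_fc` is given unless targets
#'   already are gene ids.
#' @param effect_floor Log2 effect floor standing in for a significance
#'   call on replicate-free assays.
#' @return An [evidence_matrix()].
#' @export
assemble_evidence <- function(de = NULL, array_fc = NULL, qpcr_fc = NULL,
                              extra = NULL, target_map = NULL,
                              effect_floor = 0.58) {
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  for (cmp in names(de)) {
    d <- de[[cmp]]
    add(data.frame(
      gene = d$gene_id, assay = "rnaseq", comparison = cmp,
      direction = .call_direction(d$log2fc,
                                  attr(d, "tau_de") %||% 2),
      magnitude = d$log2fc, significant = d$passes_de,
      stringsAsFactors = FALSE))
  }
  for (cmp in names(array_fc)) {
    a <- array_fc[[cmp]]
    gene <- if (is.null(target_map)) a$target
            else target_map$gene[match(a$target, target_map$target)]
    if (anyNA(gene)) {
      warning("skipping unmapped array target(s): ",
              paste(a$target[is.na(gene)], collapse = ", "))
      a <- a[!is.na(gene), , drop = FALSE]
      gene <- gene[!is.na(gene)]
    }
    add(data.frame(
      gene = gene, assay = "array", comparison = cmp,
      direction = .call_direction(a$log2_ratio, effect_floor),
      magnitude = a$log2_ratio,
      significant = abs(a$log2_ratio) >= effect_floor,
      stringsAsFactors = FALSE))
  }
  for (cmp in names(qpcr_fc)) {
    q <- qpcr_fc[[cmp]]
    add(data.frame(
      gene = q$gene, assay = "qrtpcr", comparison = cmp,
      direction = .call_direction(q$log2fc, effect_floor),
      magnitude = q$log2fc,
      significant = abs(q$log2fc) >= effect_floor,
      stringsAsFactors = FALSE))
  }
  if (!is.null(extra)) add(extra[, c("gene", "assay", "comparison",
                                     "direction", "magnitude",
                                     "significant")])
  if (!length(rows)) stop("no evidence provided")
  evidence_matrix(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rule configuration for signature derivation
#'
#' Each conjunct of the integration rule can be toggled; disabling a step
#' can only grow or preserve the resulting signature.
#'
#' @param require_preliminary Step 1: candidate must come from the
#'   preliminary (secretory, IFN-regulated, transcript-DE) list.
#' @param require_proteomic Step 2: at least one significant proteomic
#'   record in the treatment direction for `PTR_vs_P`.
#' @param require_kd_reversal Step 3: at least one significant record in
#'   the opposite direction for `KD_vs_PTR` (type-I IFN dependence).
#' @param kd_modality Modalities accepted for step 3: "any" (default;
#'   both protein array and qRT-PCR probed the knockdown comparison) or
#'   "proteomic" for the strict mode.
#' @param confirmation Step 4: "cross_modality" (default) requires at
#'   least one transcriptomic and one proteomic confirming record;
#'   "two_methods" is the weaker reading requiring two confirming assays
#'   of any modality.
#' @return A `rule_config` list.
#' @export
rule_config <- function(require_preliminary = TRUE,
                        require_proteomic = TRUE,
                        require_kd_reversal = TRUE,
                        kd_modality = c("any", "proteomic"),
                        confirmation = c("cross_modality", "two_methods",
                                         "none")) {
  structure(list(require_preliminary = require_preliminary,
                 require_proteomic = require_proteomic,
                 require_kd_reversal = require_kd_reversal,
                 kd_modality = match.arg(kd_modality),
                 confirmation = match.arg(confirmation)),
            class = "rule_config")
}

.derive <- function(ev, prelim, rules, sig_direction, name) {
  stopifnot(inherits(ev, "evidence_matrix") || is.data.frame(ev),
            inherits(rules, "rule_config"))
  up <- if (sig_direction == "up") "up" else "down"    # treatment direction
  dn <- if (sig_direction == "up") "down" else "up"    # KD-reversal direction
  candidates <- sort(unique(c(prelim, ev$gene)))
  if (!length(candidates))
    return(gene_signature(name, character(0),
                          derivation_log = data.frame()))
  by_gene <- split(seq_len(nrow(ev)), ev$gene)
  log_rows <- lapply(candidates, function(g) {
    e <- ev[by_gene[[g]] %||% integer(0), , drop = FALSE]
    confirming <- e$significant & e$direction == up &
      e$comparison == "PTR_vs_P"
    s1 <- g %in% prelim
    s2 <- any(confirming & e$modality == "proteomic")
    kd <- e$significant & e$direction == dn & e$comparison == "KD_vs_PTR"
    if (rules$kd_modality == "proteomic") kd <- kd & e$modality == "proteomic"
    s3 <- any(kd)
    s4 <- switch(rules$confirmation,
      cross_modality = any(confirming & e$modality == "transcriptomic") &&
                       any(confirming & e$modality == "proteomic"),
      two_methods = length(unique(e$assay[confirming])) >= 2,
      none = TRUE)
    pass <- (!rules$require_preliminary | s1) &
            (!rules$require_proteomic | s2) &
            (!rules$require_kd_reversal | s3) &
            s4
    data.frame(gene = g, in_preliminary = s1, proteomic_up = s2,
               kd_reversed = s3, cross_confirmed = s4, selected = pass,
               stringsAsFactors = FALSE)
  })
  dlog <- do.call(rbind, log_rows)
  rownames(dlog) <- NULL
  gene_signature(name, sort(dlog$gene[dlog$selected]), derivation_log = dlog)
}

#' Derive the upregulated secretome signature
#'
#' A gene enters the signature iff it (1) is on the preliminary list
#' (secretory, IFN-regulated, transcript up in `PTR_vs_P`), (2) has at
#' least one significant proteomic "up" record in `PTR_vs_P`, (3) has at
#' least one significant "down" record in `KD_vs_PTR` (any modality by
#' default — the IFNAR1-knockdown reversal), and (4) is confirmed by at
#' least one transcriptomic and one proteomic method overall.  Steps are
#' individually toggleable via [rule_config()].  Membership and the
#' alphabetical ordering are pure functions of the inputs.
#'
#' @param ev An [evidence_matrix()].
#' @param prelim Candidate genes from [build_preliminary_list()].
#' @param rules A [rule_config()].
#' @param name Signature name.
#' @return A `gene_signature`: list with `name`, `genes` (alphabetical),
#'   and `derivation_log` (per-candidate verdict for every step).
#' @export
derive_signature <- function(ev, prelim, rules = rule_config(),
                             name = "PTIS") {
  .derive(ev, prelim, rules, "up", name)
}

#' Derive the downregulated (mirrored) signature
#'
#' Exact mirror of [derive_signature()]: transcript and proteomic evidence
#' must point down in `PTR_vs_P` and up in `KD_vs_PTR`.  On any single
#' evidence matrix the up- and down-signatures are disjoint.
#'
#' @inheritParams derive_signature
#' @param prelim_down Candidates from
#'   `build_preliminary_list(..., direction = "down")`.
#' @return A `gene_signature`.
#' @export
derive_signature_down <- function(ev, prelim_down, rules = rule_config(),
                                  name = "PTIS_DOWN") {
  .derive(ev, prelim_down, rules, "down", name)
}

#' Gene signature container
#'
#' @param name Signature name.
#' @param genes Unique gene ids (stored sorted).
#' @param derivation_log Optional per-candidate rule verdicts.
#' @return A `gene_signature` object.
#' @export
gene_signature <- function(name, genes, derivation_log = NULL) {
  if (anyDuplicated(genes)) stop("signature genes must be unique")
  structure(list(name = name, genes = sort(as.character(genes)),
                 derivation_log = derivation_log),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("gene_signature '", x$name, "': ", length(x$genes), " gene(s)\n",
      sep = "")
  if (length(x$genes))
    cat(" ", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.gene_signature <- function(object, ...) {
  print(object)
  if (!is.null(object$derivation_log) && nrow(object$derivation_log)) {
    cat("Derivation (", nrow(object$derivation_log), " candidates):\n",
        sep = "")
    print(object$derivation_log, row.names = FALSE)
  }
  invisible(object)
}

#' Write a signature as a GMT line and its derivation log as TSV
#'
#' @param sig A `gene_signature`.
#' @param gmt_path Output GMT path.
#' @param log_path Optional derivation-log TSV path.
#' @return Paths, invisibly.
#' @export
write_signature <- function(sig, gmt_path, log_path = NULL) {
  sets <- stats::setNames(list(sig$genes), sig$name)
  write_gmt(sets, gmt_path, description = "derived signature")
  if (!is.null(log_path) && !is.null(sig$derivation_log))
    .write_tsv(sig$derivation_log, log_path)
  invisible(c(gmt_path, log_path))
}
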