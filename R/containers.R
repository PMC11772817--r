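#' Gene-by-sample count matrix with condition labels
#'
#' The root container of the expression stage: a non-negative integer
#' matrix (genes in rows, samples in columns) together with a condition
#' label per sample.
#'
#' @param counts Integer matrix with gene row names and sample column names.
#' @param condition_of Named character vector mapping every sample to a
#'   condition label.
#' @param replicate Optional named integer vector of replicate indices.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, condition_of, replicate = NULL) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      is.null(colnames(counts)))
    stop("counts must have gene row names and sample column names")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (anyDuplicated(rownames(counts))) stop("duplicated gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicated sample ids")
  if (any(counts < 0)) stop("counts must be non-negative")
  missing <- setdiff(colnames(counts), names(condition_of))
  if (length(missing))
    stop("samples without a condition: ", paste(missing, collapse = ", "))
  condition_of <- condition_of[colnames(counts)]
  structure(list(counts = counts,
                 condition_of = condition_of,
                 replicate = replicate),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples (", paste(unique(x$condition_of), collapse = ", "), ")\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Secretome + interferome annotation database
#'
#' A flat secretome membership list (GO:0005576-style extracellular-region
#' genes) and an Interferome-style record table.  A gene may carry several
#' interferome records (different IFN types and directions).
#'
#' @param secretome Character vector of secretory gene ids.
#' @param interferome data.frame with columns `gene`, `ifn_type` (one of
#'   "I", "II", "III"), `fold_change` (> 0), `direction` ("up"/"down").
#' @return An object of class `annotation_db`.
#' @export
annotation_db <- function(secretome, interferome) {
  need <- c("gene", "ifn_type", "fold_change", "direction")
  if (!all(need %in% names(interferome)))
    stop("interferome table needs columns: ", paste(need, collapse = ", "))
  if (any(!interferome$ifn_type %in% c("I", "II", "III")))
    stop("ifn_type must be I, II or III")
  if (any(interferome$fold_change <= 0))
    stop("interferome fold_change must be > 0")
  if (any(!interferome$direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'")
  structure(list(secretome = unique(as.character(secretome)),
                 interferome = interferome),
            class = "annotation_db")
}

#' @export
print.annotation_db <- function(x, ...) {
  cat("annotation_db:", length(x$secretome), "secretome genes;",
      nrow(x$interferome), "interferome records for",
      length(unique(x$interferome$gene)), "genes\n")
  invisible(x)
}

#' Multi-exposure cytokine-array experiment
#'
#' Long-format spot densitometry volumes across membranes (one per
#' condition) and film exposures.  Every membrane must carry at least one
#' positive-control (`reference`) and one `background` spot.
#'
#' @param spots data.frame with columns `membrane`, `condition`,
#'   `exposure_s`, `row`, `col`, `target`, `spot_class` (one of "target",
#'   "reference", "background"), `volume`.
#' @param saturation_ceiling Volume at which spots saturate.
#' @return An object of class `array_experiment`.
#' @export
array_experiment <- function(spots, saturation_ceiling = 65535) {
  need <- c("membrane", "condition", "exposure_s", "target",
            "spot_class", "volume")
  if (!all(need %in% names(spots)))
    stop("spots table needs columns: ", paste(need, collapse = ", "))
  if (any(!spots$spot_class %in% c("target", "reference", "background")))
    stop("spot_class must be target/reference/background")
  if (any(spots$volume < 0)) stop("volumes must be non-negative")
  for (m in unique(spots$membrane)) {
    cls <- spots$spot_class[spots$membrane == m]
    if (!any(cls == "reference") || !any(cls == "background"))
      stop("membrane ", m, " lacks reference or background spots")
  }
  structure(list(spots = spots, saturation_ceiling = saturation_ceiling),
            class = "array_experiment")
}

#' @export
print.array_experiment <- function(x, ...) {
  tg <- unique(x$spots$target[x$spots$spot_class == "target"])
  cat("array_experiment:", length(tg), "targets,",
      length(unique(x$spots$membrane)), "membranes,",
      length(unique(x$spots$exposure_s)), "exposures (ceiling",
      x$saturation_ceiling, ")\n")
  invisible(x)
}

#' qRT-PCR CT table
#'
#' CT values per (gene, sample), a non-empty housekeeping gene set (each
#' sample must have a CT for every housekeeping gene), and a sample ->
#' condition map.
#'
#' @param ct data.frame with columns `gene`, `sample`, `ct`.
#' @param housekeeping_genes Non-empty character vector.
#' @param condition_of Named character vector mapping samples to conditions.
#' @return An object of class `ct_table`.
#' @export
ct_table <- function(ct, housekeeping_genes, condition_of) {
  if (!all(c("gene", "sample", "ct") %in% names(ct)))
    stop("ct table needs columns gene, sample, ct")
  if (!length(housekeeping_genes)) stop("need >= 1 housekeeping gene")
  if (any(!is.finite(ct$ct))) stop("CT values must be finite")
  for (s in unique(ct$sample)) {
    have <- ct$gene[ct$sample == s]
    if (!all(housekeeping_genes %in% have))
      stop("sample ", s, " lacks housekeeping CT(s)")
  }
  missing <- setdiff(unique(ct$sample), names(condition_of))
  if (length(missing))
    stop("samples without a condition: ", paste(missing, collapse = ", "))
  structure(list(ct = ct,
                 housekeeping_genes = housekeeping_genes,
                 condition_of = condition_of),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat("ct_table:", length(setdiff(unique(x$ct$gene), x$housekeeping_genes)),
      "genes +", length(x$housekeeping_genes), "housekeeping, ",
      length(unique(x$ct$sample)), "samples\n")
  invisible(x)
}
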