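# Plain-text readers/writers for the pipeline's interchange formats.
# All tables are written with headers, tab- (or comma-) separated, no
# quoting, so outputs diff cleanly and re-runs are byte-identical.

.write_tsv <- function(x, path, sep = "\t") {
  utils::write.table(x, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a count matrix as TSV
#'
#' Counts go to `counts_path` (first column `gene`, one column per sample);
#' the sample table (`sample`, `condition`, `replicate`) to `samples_path`.
#'
#' @param x A [count_matrix()].
#' @param counts_path,samples_path Output (input) file paths.
#' @return `write_count_matrix()` returns the paths invisibly;
#'   `read_count_matrix()` returns a [count_matrix()].
#' @export
write_count_matrix <- function(x, counts_path, samples_path) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(gene = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(tab, counts_path)
  smp <- data.frame(sample = names(x$condition_of),
                    condition = unname(x$condition_of),
                    replicate = if (is.null(x$replicate)) NA_integer_
                                else unname(x$replicate[names(x$condition_of)]),
                    stringsAsFactors = FALSE)
  .write_tsv(smp, samples_path)
  invisible(c(counts_path, samples_path))
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab$gene
  smp <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  rep_v <- if ("replicate" %in% names(smp) && !all(is.na(smp$replicate)))
    stats::setNames(smp$replicate, smp$sample) else NULL
  count_matrix(counts, stats::setNames(smp$condition, smp$sample),
               replicate = rep_v)
}

#' Write / read an annotation database
#'
#' The secretome goes out both as a one-gene-per-line text file and as a
#' single GMT line; the interferome as TSV (gene, ifn_type, fold_change,
#' direction).
#'
#' @param db An [annotation_db()].
#' @param secretome_path,interferome_path File paths (`.txt`/`.tsv`).
#' @param gmt_path Optional path for the secretome as a GMT line.
#' @return Paths invisibly; `read_annotation_db()` returns an
#'   [annotation_db()].
#' @export
write_annotation_db <- function(db, secretome_path, interferome_path,
                                gmt_path = NULL) {
  stopifnot(inherits(db, "annotation_db"))
  writeLines(db$secretome, secretome_path)
  .write_tsv(db$interferome, interferome_path)
  if (!is.null(gmt_path))
    write_gmt(list(secretome = db$secretome), gmt_path,
              description = "extracellular region (GO:0005576-style)")
  invisible(c(secretome_path, interferome_path, gmt_path))
}

#' @rdname write_annotation_db
#' @export
read_annotation_db <- function(secretome_path, interferome_path) {
  annotation_db(readLines(secretome_path),
                utils::read.delim(interferome_path, stringsAsFactors = FALSE))
}

#' Write / read an array experiment as long-format CSV
#'
#' @param x An [array_experiment()].
#' @param path CSV path.
#' @param saturation_ceiling Ceiling to attach on read.
#' @return Path invisibly; `read_array_experiment()` returns an
#'   [array_experiment()].
#' @export
write_array_experiment <- function(x, path) {
  stopifnot(inherits(x, "array_experiment"))
  .write_tsv(x$spots, path, sep = ",")
}

#' @rdname write_array_experiment
#' @export
read_array_experiment <- function(path, saturation_ceiling = 65535) {
  array_experiment(utils::read.csv(path, stringsAsFactors = FALSE),
                   saturation_ceiling)
}

#' Write / read a CT table as TSV
#'
#' The housekeeping gene set and sample conditions are carried in side
#' columns (`is_housekeeping`, `condition`) so one file round-trips the
#' whole object.
#'
#' @param x A [ct_table()].
#' @param path TSV path.
#' @return Path invisibly; `read_ct_table()` returns a [ct_table()].
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_table"))
  tab <- x$ct
  tab$is_housekeeping <- tab$gene %in% x$housekeeping_genes
  tab$condition <- unname(x$condition_of[tab$sample])
  .write_tsv(tab, path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  hk <- unique(tab$gene[tab$is_housekeeping])
  cond <- tab[!duplicated(tab$sample), c("sample", "condition")]
  ct_table(tab[c("gene", "sample", "ct")], hk,
           stats::setNames(cond$condition, cond$sample))
}

#' Read and write GMT gene-set files
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param sets Named list of character vectors (gene sets).
#' @param path File path.
#' @param description Description field written for every set.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
write_gmt <- function(sets, path, description = "") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' Read and write RNK ranked-list files
#'
#' Two tab-separated columns, gene and metric, no header.  On read the list
#' is re-sorted with the package's deterministic ordering (metric
#' descending, ties broken by gene id).
#'
#' @param ranked A ranked list (data.frame with `gene`, `metric`).
#' @param path File path.
#' @return `read_rnk()` returns a `ranked_list` data.frame.
#' @export
write_rnk <- function(ranked, path) {
  utils::write.table(ranked[, c("gene", "metric")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_rnk
#' @export
read_rnk <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("gene", "metric"))
  .as_ranked_list(tab)
}
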