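# Shared fixtures, all built in code.

# ranked list through the exported path (build_rank_list wants a DE table)
make_ranked <- function(genes, metrics) {
  build_rank_list(data.frame(gene_id = genes, log2fc = metrics,
                             stringsAsFactors = FALSE))
}

# a normalized_expression object with known CPM values
make_ne <- function(cpm, condition_of) {
  structure(list(cpm = cpm,
                 uq_factors = stats::setNames(rep(1, ncol(cpm)),
                                              colnames(cpm)),
                 lib_sizes = colSums(cpm),
                 condition_of = condition_of[colnames(cpm)]),
            class = "normalized_expression")
}

# a DE table with chosen log2fcs (passes_de at |lfc| >= tau)
make_de <- function(genes, lfc, tau = 2) {
  out <- data.frame(gene_id = genes, mean_cpm_ref = 10,
                    mean_cpm_test = 10 * 2^lfc, log2fc = lfc,
                    passes_de = abs(lfc) >= tau, stringsAsFactors = FALSE)
  attr(out, "tau_de") <- tau
  class(out) <- c("de_results", "data.frame")
  out
}

# small hand-built annotation database
make_db <- function(secretome, ifn_genes, fold_change = 2,
                    ifn_type = "I", direction = "up") {
  tab <- if (length(ifn_genes))
    data.frame(gene = ifn_genes, ifn_type = ifn_type,
               fold_change = fold_change, direction = direction,
               stringsAsFactors = FALSE)
  else
    data.frame(gene = character(0), ifn_type = character(0),
               fold_change = numeric(0), direction = character(0),
               stringsAsFactors = FALSE)
  annotation_db(secretome, tab)
}

# one hand-built membrane: duplicate target spots, reference, background
make_membrane <- function(condition, exposure_s, target_vols,
                          ref_vol = 1000, bg_vol = 20) {
  targets <- names(target_vols)
  do.call(rbind, c(
    lapply(seq_along(targets), function(i)
      data.frame(membrane = paste0("mem_", condition), condition = condition,
                 exposure_s = exposure_s, row = i, col = 1:2,
                 target = targets[i], spot_class = "target",
                 volume = rep(target_vols[[i]], 2),
                 stringsAsFactors = FALSE)),
    list(data.frame(membrane = paste0("mem_", condition),
                    condition = condition, exposure_s = exposure_s,
                    row = 0, col = 1:2, target = NA_character_,
                    spot_class = c("reference", "background"),
                    volume = c(ref_vol, bg_vol),
                    stringsAsFactors = FALSE))))
}

# brute-force unweighted (p = 0) enrichment statistic: at each list
# position, the difference between the fraction of set members and the
# fraction of non-members seen so far; the statistic is the extremum of
# maximal absolute deviation, ties in magnitude going to the negative one
# (the package-wide convention).  Plain double loop, independent of the
# package's weighted running-sum code path.
es_oracle_p0 <- function(hit_positions, n) {
  k <- length(hit_positions)
  top <- bottom <- 0
  for (i in seq_len(n)) {
    p_hit <- sum(hit_positions <= i) / k
    p_miss <- (i - sum(hit_positions <= i)) / (n - k)
    d <- p_hit - p_miss
    if (d > top) top <- d
    if (d < bottom) bottom <- d
  }
  if (top + bottom > 1e-12) top else bottom
}
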