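# Preranked gene-set enrichment, implemented from scratch: weighted
# Kolmogorov-Smirnov-style running sum (ES), gene-set permutation null,
# sign-matched NES, and a sign-stratified ratio-of-tails FDR q.

#' Weighted running-sum enrichment score
#'
#' Walking down the ranked list, the running sum gains
#' `|metric|^p / sum(|metric|^p over hits)` at each set member and loses
#' `1 / (N - N_hits)` at each non-member; the enrichment score is the
#' running-sum value of maximal absolute deviation.  When the positive and
#' negative extrema tie in magnitude (common at p = 0) the negative one is
#' taken, the convention of the reference implementations; the comparison
#' uses a 1e-12 guard so accumulated rounding cannot flip it.  At `p = 0`
#' this is the classical Kolmogorov-Smirnov-style
#' statistic and is invariant to strictly monotone rescaling of the
#' metric.  If all hit weights are zero (possible at p > 0 with zero
#' metrics) equal weights are used.
#'
#' @param r A `ranked_list` (from [build_rank_list()] or [read_rnk()]).
#' @param genes Gene set (character vector); must overlap the ranked
#'   universe and must not cover it entirely.
#' @param p Weight exponent, >= 0 (default 1, the conventional weighting).
#' @return List: `es` (in \[-1, 1\]), `running_sum` (length-N numeric),
#'   `leading_edge` (set members at or before the extremum; after it for
#'   negative ES), `hit_indices`.
#' @export
enrichment_score <- function(r, genes, p = 1) {
  stopifnot(inherits(r, "ranked_list") || is.data.frame(r), p >= 0)
  hit <- r$gene %in% genes
  N <- length(hit); Nh <- sum(hit)
  if (Nh == 0) stop("gene set has no member in the ranked universe")
  if (Nh == N)
    stop("gene set covers the entire universe; miss decrement undefined")
  w <- abs(r$metric)^p
  w[!hit] <- 0
  W <- sum(w)
  if (W == 0) { w[hit] <- 1; W <- Nh }
  step <- ifelse(hit, w / W, -1 / (N - Nh))
  running <- cumsum(step)
  es <- .pick_extremum(max(running), min(running))
  i <- if (es >= 0) which.max(running) else which.min(running)
  le <- if (es >= 0) r$gene[hit & seq_len(N) <= i]
        else r$gene[hit & seq_len(N) >= i]
  list(es = es, running_sum = running, leading_edge = le,
       hit_indices = which(hit))
}

# extremum choice shared by every ES code path: ties in magnitude go to
# the negative extremum, with a tolerance so rounding cannot flip them
.pick_extremum <- function(top, bottom) {
  if (top + bottom > 1e-12) top else bottom
}

# ES from sorted hit positions only (O(n_hits)); same statistic as
# enrichment_score, used for the permutation null.  `w_all` is the full
# |metric|^p vector in rank order.
.es_from_positions <- function(pos, w_all, N) {
  k <- length(pos)
  w <- w_all[pos]
  W <- sum(w)
  if (W == 0) { w <- rep(1, k); W <- k }
  cw <- cumsum(w) / W
  miss <- (pos - seq_len(k)) / (N - k)
  before <- c(0, cw[-k]) - miss   # value just before each hit
  after <- cw - miss              # value at each hit
  # the running sum ends at exactly 0, so 0 is always an attained value
  .pick_extremum(max(c(after, 0)), min(c(before, 0)))
}

#' Preranked GSEA with gene-set permutation FDR
#'
#' For every gene set, the null distribution of the enrichment score is
#' built from `n_perm` random same-size gene sets drawn without
#' replacement from the ranked universe.  NES divides the observed ES by
#' the mean |null ES| of matching sign; q-values come from the
#' sign-stratified ratio-of-tails estimator (fraction of pooled null NES
#' at or beyond the observed NES, divided by the fraction of observed NES
#' at or beyond it), clipped to \[0, 1\].  Each set has its own RNG
#' stream, seeded from the global seed and the set's index, so results do
#' not depend on which other sets are evaluated first.
#'
#' @param r A `ranked_list`.
#' @param sets Named list of gene sets (character vectors), e.g. from
#'   [read_gmt()].
#' @param n_perm Number of gene-set permutations (default 1000).
#' @param p Weight exponent (default 1).
#' @param seed Integer seed for the permutation streams.
#' @param fdr_cutoff Reporting threshold stored on the result (the
#'   conventional 0.25).
#' @return A `gsea_results` data.frame: set, size (overlap with the
#'   universe), es, nes, fdr_q, n_perm, leading_edge
#'   (comma-collapsed).  Sets with zero overlap are returned flagged
#'   (`size` 0, es/nes/fdr_q NA) and excluded from the FDR pool.
#' @export
gsea_preranked <- function(r, sets, n_perm = 1000, p = 1, seed = 1L,
                           fdr_cutoff = 0.25) {
  stopifnot(n_perm >= 1)
  if (is.character(sets)) sets <- list(set = sets)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("gene sets must be named")
  N <- nrow(r)
  w_all <- abs(r$metric)^p
  res <- vector("list", length(sets))
  null_nes <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    overlap <- intersect(sets[[i]], r$gene)
    k <- length(overlap)
    if (k == 0 || k == N) {
      res[[i]] <- data.frame(set = names(sets)[i], size = k,
                             es = NA_real_, nes = NA_real_,
                             fdr_q = NA_real_, n_perm = n_perm,
                             leading_edge = "", stringsAsFactors = FALSE)
      next
    }
    obs <- enrichment_score(r, overlap, p)
    set.seed((seed + 7919L * i) %% .Machine$integer.max)
    null_es <- vapply(seq_len(n_perm), function(b)
      .es_from_positions(sort.int(sample.int(N, k)), w_all, N), numeric(1))
    norm_of <- function(es_vals) {
      pos_mean <- mean(abs(null_es[null_es >= 0]))
      neg_mean <- mean(abs(null_es[null_es < 0]))
      ifelse(es_vals >= 0, es_vals / pos_mean, es_vals / neg_mean)
    }
    nes <- norm_of(obs$es)
    null_nes[[i]] <- norm_of(null_es)
    res[[i]] <- data.frame(set = names(sets)[i], size = k, es = obs$es,
                           nes = nes, fdr_q = NA_real_, n_perm = n_perm,
                           leading_edge = paste(obs$leading_edge,
                                                collapse = ","),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  pool <- unlist(null_nes)
  pool <- pool[is.finite(pool)]
  obs_nes <- out$nes[is.finite(out$nes)]
  for (i in seq_len(nrow(out))) {
    nes <- out$nes[i]
    if (!is.finite(nes)) next
    if (nes >= 0) {
      num <- if (any(pool >= 0)) mean(pool[pool >= 0] >= nes) else 0
      den <- mean(obs_nes[obs_nes >= 0] >= nes)
    } else {
      num <- if (any(pool < 0)) mean(pool[pool < 0] <= nes) else 0
      den <- mean(obs_nes[obs_nes < 0] <= nes)
    }
    out$fdr_q[i] <- min(1, max(0, num / den))
  }
  attr(out, "seed") <- seed
  attr(out, "p") <- p
  attr(out, "fdr_cutoff") <- fdr_cutoff
  class(out) <- c("gsea_results", "data.frame")
  out
}

#' @export
print.gsea_results <- function(x, ...) {
  cat("gsea_results (", nrow(x), " sets, ", x$n_perm[1],
      " gene-set permutations, seed ", attr(x, "seed"), "):\n", sep = "")
  print(as.data.frame(x[, c("set", "size", "es", "nes", "fdr_q")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Per-sample average-CPM signature score
#'
#' Arithmetic mean CPM over the set genes present in the expression
#' matrix, per sample.  Missing set genes are reported in the
#' `missing_genes` attribute; a set with zero overlap is an error.
#'
#' @param e A `normalized_expression` from [upper_quartile_normalize()].
#' @param genes Gene set (character vector or `gene_signature`).
#' @return Named numeric vector of per-sample scores.
#' @export
average_cpm_score <- function(e, genes) {
  stopifnot(inherits(e, "normalized_expression"))
  if (inherits(genes, "gene_signature")) genes <- genes$genes
  present <- intersect(genes, rownames(e$cpm))
  if (!length(present)) stop("no signature gene present in the matrix")
  scores <- colMeans(e$cpm[present, , drop = FALSE])
  attr(scores, "missing_genes") <- setdiff(genes, present)
  scores
}

#' Compare signature scores between two groups (Welch t-test)
#'
#' Difference of means (test minus ref) with the two-sided Welch
#' unequal-variance t-test.  With a single sample on either side only the
#' difference is returned; when both groups are constant and equal the
#' p-value is 1 by convention (0 when constant but different).
#'
#' @param scores_test,scores_ref Numeric score vectors.
#' @return List: `difference`, `t`, `df`, `p_value`.
#' @export
compare_scores <- function(scores_test, scores_ref) {
  diff <- mean(scores_test) - mean(scores_ref)
  if (length(scores_test) < 2 || length(scores_ref) < 2)
    return(list(difference = diff, t = NA_real_, df = NA_real_,
                p_value = NA_real_))
  if (stats::var(scores_test) == 0 && stats::var(scores_ref) == 0)
    return(list(difference = diff, t = if (diff == 0) 0 else Inf,
                df = NA_real_, p_value = if (diff == 0) 1 else 0))
  tt <- stats::t.test(scores_test, scores_ref, var.equal = FALSE)
  list(difference = diff, t = unname(tt$statistic),
       df = unname(tt$parameter), p_value = tt$p.value)
}
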