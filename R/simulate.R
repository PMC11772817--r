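#' Simulation configuration for the multi-omic synthetic data generator
#'
#' Defines a four-condition experiment (parental `P`, treatment-resistant
#' `PTR`, and their IFNAR1-knockdown counterparts `P_KD`, `PTR_KD`) with a
#' planted set of "true" signature genes that are secretory, type-I
#' IFN-regulated, and upregulated in `PTR`.  All generators
#' ([simulate_counts()], [simulate_annotation()], [simulate_array()],
#' [simulate_qpcr()]) are pure functions of this configuration: the single
#' `seed` fans out to fixed per-assay child seeds so that changing one
#' assay's structure never reshuffles another assay's draws.
#'
#' @param n_genes Number of simulated genes.
#' @param n_per_group Biological replicates per condition.
#' @param conditions Ordered subset of `c("P", "PTR", "P_KD", "PTR_KD")`.
#' @param planted_genes Character vector of gene ids designated as true
#'   signature members, or a single integer giving how many genes from the
#'   start of the universe to plant.  All planted genes are annotated
#'   secretory and type-I IFN-regulated by [simulate_annotation()].
#' @param planted_log2fc Treatment effect (log2 scale) of planted genes in
#'   `PTR` vs `P`.
#' @param kd_reversal Fraction in \[0, 1\] of the planted effect removed in
#'   `PTR_KD`; 1 means knockdown fully reverses the treatment effect.
#' @param nb_dispersion Negative-binomial dispersion (Var = mu + disp * mu^2).
#' @param baseline_log2_mean_range Range (pair) for per-gene baseline log2
#'   mean counts, drawn uniformly.
#' @param secretome_fraction Fraction of genes annotated secretory.
#' @param ifn_fraction Fraction of non-planted genes carrying a type-I "up"
#'   interferome record at or above the 1.5 fold-change threshold.
#' @param libsize_log_sd Log-scale SD of per-sample library-size factors
#'   (log-normal), so that normalization is non-trivial.
#' @param array_exposures Film exposure times (seconds) simulated for the
#'   cytokine array; volumes scale linearly with exposure.
#' @param array_targets_extra Number of non-planted genes also spotted on
#'   the array (planted genes are always spotted).
#' @param saturation_ceiling Detector/film saturation ceiling for spot
#'   volumes.
#' @param array_noise_sd Log-normal SD of per-spot multiplicative noise.
#' @param qpcr_noise_sd Gaussian technical noise of CT values, in cycles.
#' @param qpcr_extra_genes Number of non-planted genes also assayed by
#'   qRT-PCR.
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_counts()], [simulate_annotation()],
#'   [simulate_array()], [simulate_qpcr()]
#' @export
#' @examples
#' cfg <- simulation_config(n_genes = 200, planted_genes = 10, seed = 1)
#' cfg
simulation_config <- function(n_genes = 2000,
                              n_per_group = 3,
                              conditions = c("P", "PTR", "P_KD", "PTR_KD"),
                              planted_genes = 50,
                              planted_log2fc = 3,
                              kd_reversal = 1,
                              nb_dispersion = 0.2,
                              baseline_log2_mean_range = c(3, 10),
                              secretome_fraction = 0.25,
                              ifn_fraction = 0.3,
                              libsize_log_sd = 0.2,
                              array_exposures = c(1, 4, 16),
                              array_targets_extra = 50,
                              saturation_ceiling = 65535,
                              array_noise_sd = 0.1,
                              qpcr_noise_sd = 0.15,
                              qpcr_extra_genes = 20,
                              seed = 1L) {
  known <- c("P", "PTR", "P_KD", "PTR_KD")
  bad <- setdiff(conditions, known)
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(conditions))
    stop("duplicated condition labels")
  if (n_genes < 1 || n_per_group < 1)
    stop("n_genes and n_per_group must be >= 1")
  universe <- sprintf("g%05d", seq_len(n_genes))
  if (is.numeric(planted_genes) && length(planted_genes) == 1L) {
    if (planted_genes > n_genes)
      stop("more planted genes than genes in the universe")
    planted_genes <- universe[seq_len(planted_genes)]
  }
  planted_genes <- as.character(planted_genes)
  if (!all(planted_genes %in% universe))
    stop("planted gene(s) outside the simulated gene universe: ",
         paste(setdiff(planted_genes, universe), collapse = ", "))
  if (anyDuplicated(planted_genes)) stop("duplicated planted genes")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (kd_reversal < 0 || kd_reversal > 1)
    stop("kd_reversal must lie in [0, 1]")
  for (f in c(secretome_fraction, ifn_fraction))
    if (f <= 0 || f >= 1) stop("fractions must lie in (0, 1)")
  if (length(baseline_log2_mean_range) != 2L ||
      diff(baseline_log2_mean_range) < 0)
    stop("baseline_log2_mean_range must be an increasing pair")
  if (length(array_exposures) < 2L || any(array_exposures <= 0))
    stop("need >= 2 positive array exposures")
  if (saturation_ceiling <= 0) stop("saturation_ceiling must be > 0")
  if (qpcr_noise_sd < 0 || array_noise_sd < 0 || libsize_log_sd < 0)
    stop("noise SDs must be >= 0")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  structure(list(
    n_genes = as.integer(n_genes),
    n_per_group = as.integer(n_per_group),
    conditions = conditions,
    universe = universe,
    planted_genes = planted_genes,
    planted_log2fc = planted_log2fc,
    kd_reversal = kd_reversal,
    nb_dispersion = nb_dispersion,
    baseline_log2_mean_range = baseline_log2_mean_range,
    secretome_fraction = secretome_fraction,
    ifn_fraction = ifn_fraction,
    libsize_log_sd = libsize_log_sd,
    array_exposures = sort(array_exposures),
    array_targets_extra = as.integer(array_targets_extra),
    saturation_ceiling = saturation_ceiling,
    array_noise_sd = array_noise_sd,
    qpcr_noise_sd = qpcr_noise_sd,
    qpcr_extra_genes = as.integer(qpcr_extra_genes),
    seed = seed
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_genes, "genes,",
      length(x$planted_genes), "planted (log2FC", x$planted_log2fc,
      "),", x$n_per_group, "per group x",
      paste(x$conditions, collapse = "/"),
      "| seed", x$seed, "\n")
  invisible(x)
}

# fixed offsets fanning the global seed out to per-assay streams
.child_seed <- function(cfg, assay) {
  off <- c(counts = 101L, annotation = 211L, array = 307L, qpcr = 401L,
           means = 503L)
  (cfg$seed + off[[assay]]) %% .Machine$integer.max
}

# per-gene condition effect on the log2 scale
.condition_effect <- function(cfg, condition) {
  planted <- cfg$universe %in% cfg$planted_genes
  eff <- numeric(cfg$n_genes)
  if (condition == "PTR") eff[planted] <- cfg$planted_log2fc
  if (condition == "PTR_KD")
    eff[planted] <- cfg$planted_log2fc * (1 - cfg$kd_reversal)
  eff
}

# baseline log2 mean counts, shared by the count and qPCR generators
.baseline_log2_means <- function(cfg) {
  set.seed(.child_seed(cfg, "means"))
  r <- cfg$baseline_log2_mean_range
  stats::setNames(stats::runif(cfg$n_genes, r[1], r[2]), cfg$universe)
}

#' Simulate a negative-binomial RNA-seq count matrix
#'
#' Counts are drawn per gene and sample from a negative binomial with
#' Var = mu + dispersion * mu^2.  Baseline log2 mean counts are uniform in
#' the configured range; planted genes carry the configured log2
#' fold-change in `PTR` vs `P` (attenuated by `kd_reversal` in `PTR_KD`),
#' and per-sample library-size factors are log-normal so library-size
#' normalization is exercised downstream.
#'
#' @param config A [simulation_config()].
#' @return A [count_matrix()] with samples named `<condition>_<replicate>`.
#' @export
#' @examples
#' cfg <- simulation_config(n_genes = 100, planted_genes = 5, seed = 1)
#' m <- simulate_counts(cfg)
#' m
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mu0 <- .baseline_log2_means(config)
  set.seed(.child_seed(config, "counts"))
  samples <- data.frame(
    sample = unlist(lapply(config$conditions, function(cc)
      paste0(cc, "_", seq_len(config$n_per_group)))),
    condition = rep(config$conditions, each = config$n_per_group),
    replicate = rep(seq_len(config$n_per_group),
                    times = length(config$conditions)),
    stringsAsFactors = FALSE
  )
  n_s <- nrow(samples)
  size_factors <- exp(stats::rnorm(n_s, 0, config$libsize_log_sd))
  counts <- matrix(0L, nrow = config$n_genes, ncol = n_s,
                   dimnames = list(config$universe, samples$sample))
  for (j in seq_len(n_s)) {
    eff <- .condition_effect(config, samples$condition[j])
    mu <- 2^(mu0 + eff) * size_factors[j]
    counts[, j] <- stats::rnbinom(config$n_genes,
                                  mu = mu, size = 1 / config$nb_dispersion)
  }
  count_matrix(counts, stats::setNames(samples$condition, samples$sample),
               replicate = stats::setNames(samples$replicate, samples$sample))
}

#' Simulate secretome and interferome annotation tables
#'
#' Emulates a flat extracellular-region (GO:0005576-style) membership list
#' and an Interferome-style table of (gene, IFN type, fold change,
#' direction) records.  Every planted gene is a secretome member and has a
#' type-I "up" record with fold change >= 1.5; non-planted genes carry a
#' type-I up record with probability `ifn_fraction` and, independently, a
#' type-II record (random direction) at half that rate.
#'
#' @param config A [simulation_config()].
#' @return An `annotation_db`: list with `secretome` (character vector) and
#'   `interferome` (data.frame: gene, ifn_type, fold_change, direction).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.child_seed(config, "annotation"))
  n_sec <- round(config$secretome_fraction * config$n_genes)
  non_planted <- setdiff(config$universe, config$planted_genes)
  n_extra <- max(0L, n_sec - length(config$planted_genes))
  secretome <- sort(c(config$planted_genes,
                      sample(non_planted, min(n_extra, length(non_planted)))))
  rec <- list(data.frame(
    gene = config$planted_genes, ifn_type = "I",
    fold_change = stats::runif(length(config$planted_genes), 2, 8),
    direction = "up", stringsAsFactors = FALSE
  ))
  t1 <- non_planted[stats::runif(length(non_planted)) < config$ifn_fraction]
  if (length(t1))
    rec <- c(rec, list(data.frame(
      gene = t1, ifn_type = "I",
      fold_change = stats::runif(length(t1), 1.5, 8),
      direction = "up", stringsAsFactors = FALSE
    )))
  t2 <- config$universe[stats::runif(config$n_genes) < config$ifn_fraction / 2]
  if (length(t2))
    rec <- c(rec, list(data.frame(
      gene = t2, ifn_type = "II",
      fold_change = stats::runif(length(t2), 1.5, 8),
      direction = sample(c("up", "down"), length(t2), replace = TRUE),
      stringsAsFactors = FALSE
    )))
  interferome <- do.call(rbind, rec)
  interferome <- interferome[order(interferome$gene, interferome$ifn_type), ]
  rownames(interferome) <- NULL
  annotation_db(secretome, interferome)
}

#' Simulate a multi-exposure cytokine antibody array
#'
#' One membrane per condition, photographed at the configured exposure
#' times; signal (target and positive-control) spot volumes scale
#' linearly with exposure and clip at the saturation ceiling, while
#' background spots are constant film fog — longer exposures therefore
#' rescue weak targets until saturation, which is what makes
#' shortest-detected-exposure selection meaningful.  Each membrane
#' carries duplicate spots per protein target, positive-control reference
#' spots, and background spots.  Planted genes' targets carry the planted
#' effect in `PTR` (attenuated in `PTR_KD`).
#'
#' @param config A [simulation_config()].
#' @return An `array_experiment`: list with `spots` (long data.frame:
#'   membrane, condition, exposure_s, row, col, target, spot_class, volume)
#'   and `saturation_ceiling`.
#' @export
simulate_array <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.child_seed(config, "array"))
  non_planted <- setdiff(config$universe, config$planted_genes)
  targets <- c(config$planted_genes,
               sample(non_planted,
                      min(config$array_targets_extra, length(non_planted))))
  targets <- sort(targets)
  # latent per-target abundance (arbitrary densitometry units at 1 s)
  base <- stats::setNames(2^stats::runif(length(targets), 5, 9), targets)
  ref_level <- 3000   # positive-control spot abundance
  bg_level <- 20      # film background per second of exposure
  n_ref <- 4L; n_bg <- 4L
  out <- list()
  for (cond in config$conditions) {
    eff <- stats::setNames(.condition_effect(config, cond), config$universe)
    abundance <- base * 2^eff[targets]
    # duplicate target spots + reference + background; noise drawn once per
    # physical spot so exposures of one membrane share it (film re-exposure)
    noise_t <- matrix(exp(stats::rnorm(2 * length(targets), 0,
                                       config$array_noise_sd)),
                      nrow = length(targets))
    noise_r <- exp(stats::rnorm(n_ref, 0, config$array_noise_sd))
    noise_b <- exp(stats::rnorm(n_bg, 0, config$array_noise_sd))
    for (ex in config$array_exposures) {
      vol_t <- cbind(abundance * noise_t[, 1], abundance * noise_t[, 2]) * ex
      vol_r <- ref_level * noise_r * ex
      vol_b <- bg_level * noise_b      # film fog: exposure-independent
      spot <- data.frame(
        membrane = paste0("mem_", cond),
        condition = cond,
        exposure_s = ex,
        row = c(rep(seq_along(targets), 2), rep(0L, n_ref + n_bg)),
        col = c(rep(1:2, each = length(targets)), seq_len(n_ref),
                n_ref + seq_len(n_bg)),
        target = c(rep(targets, 2), rep(NA_character_, n_ref + n_bg)),
        spot_class = c(rep("target", 2 * length(targets)),
                       rep("reference", n_ref), rep("background", n_bg)),
        volume = pmin(c(vol_t[, 1], vol_t[, 2], vol_r, vol_b),
                      config$saturation_ceiling),
        stringsAsFactors = FALSE
      )
      out[[length(out) + 1L]] <- spot
    }
  }
  spots <- do.call(rbind, out)
  rownames(spots) <- NULL
  array_experiment(spots, config$saturation_ceiling)
}

#' Simulate a qRT-PCR CT table
#'
#' CT values per (gene, sample) with two stable housekeeping genes
#' (`Gapdh`-like `hk1`, `Actb`-like `hk2`).  One log2 unit of expression
#' equals one cycle: planted genes' CTs drop by `planted_log2fc` cycles in
#' `PTR` (attenuated in `PTR_KD`).  Gaussian technical noise with
#' `qpcr_noise_sd` cycles; at SD 0 the table is exactly noiseless.
#'
#' @param config A [simulation_config()].
#' @return A `ct_table`: list with `ct` (data.frame gene, sample, ct),
#'   `housekeeping_genes`, and `condition_of` (named character).
#' @export
simulate_qpcr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.child_seed(config, "qpcr"))
  hk <- c("hk1", "hk2")
  non_planted <- setdiff(config$universe, config$planted_genes)
  genes <- c(config$planted_genes,
             sample(non_planted,
                    min(config$qpcr_extra_genes, length(non_planted))))
  genes <- sort(genes)
  base_ct <- stats::setNames(stats::runif(length(genes), 22, 30), genes)
  hk_ct <- stats::setNames(c(19, 21), hk)
  samples <- unlist(lapply(config$conditions, function(cc)
    paste0(cc, "_", seq_len(config$n_per_group))))
  condition_of <- stats::setNames(
    rep(config$conditions, each = config$n_per_group), samples)
  rows <- list()
  for (s in samples) {
    eff <- stats::setNames(.condition_effect(config, condition_of[[s]]),
                           config$universe)
    ct_g <- base_ct - eff[genes] +
      stats::rnorm(length(genes), 0, config$qpcr_noise_sd)
    ct_h <- hk_ct + stats::rnorm(length(hk), 0, config$qpcr_noise_sd)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = c(genes, hk), sample = s, ct = c(ct_g, ct_h),
      stringsAsFactors = FALSE
    )
  }
  ct <- do.call(rbind, rows)
  rownames(ct) <- NULL
  ct_table(ct, housekeeping_genes = hk, condition_of = condition_of)
}
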