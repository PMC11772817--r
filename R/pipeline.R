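# End-to-end orchestration: simulate -> de -> array -> qpcr -> derive ->
# gsea/score, with a JSON run manifest (seed, thresholds, per-stage record
# counts, file hashes) so a run is auditable and reproducible.

.PIPELINE_DEFAULTS <- list(
  out_dir = NULL,
  seed = 1L,
  counts_path = NULL,
  samples_path = NULL,
  tau_de = 2,
  tau_ifn = 1.5,
  pseudocount = 1,
  min_cpm = 1,
  min_samples = NULL,
  detect_threshold = NULL,
  effect_floor = 0.58,
  array_pseudo = 0.01,
  qpcr_convention = "standard",
  fdr_cutoff = 0.25,
  n_perm = 1000L,
  stages = c("simulate", "de", "array", "qpcr", "derive", "gsea", "score"),
  sim = list(),
  rules = list()
)

#' Validate a pipeline configuration
#'
#' Accepts a JSON string, a JSON file path, or a list; fills defaults,
#' rejects unknown keys by name, checks threshold invariants, and warns on
#' low permutation counts (< 100).
#'
#' @param raw JSON string, path to a JSON file, or a named list.
#' @return A `pipeline_config` list.
#' @export
#' @examples
#' cfg <- validate_config(list(out_dir = tempfile(), seed = 7))
validate_config <- function(raw = list()) {
  if (is.character(raw) && length(raw) == 1) {
    raw <- if (file.exists(raw)) jsonlite::read_json(raw, simplifyVector = TRUE)
           else jsonlite::fromJSON(raw, simplifyVector = TRUE)
  }
  if (!is.list(raw)) stop("config must be a list or JSON object")
  unknown <- setdiff(names(raw), names(.PIPELINE_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.PIPELINE_DEFAULTS, raw, keep.null = TRUE)
  sim_ok <- names(formals(simulation_config))
  bad <- setdiff(names(cfg$sim), sim_ok)
  if (length(bad))
    stop("unknown sim key(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(names(cfg$rules), names(formals(rule_config)))
  if (length(bad))
    stop("unknown rules key(s): ", paste(bad, collapse = ", "))
  for (k in c("tau_de", "tau_ifn", "pseudocount", "fdr_cutoff"))
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0)
      stop(k, " must be a positive number")
  if (cfg$n_perm < 1) stop("n_perm must be >= 1")
  if (cfg$n_perm < 100)
    warning("n_perm = ", cfg$n_perm,
            ": permutation FDR will be coarse below 100 permutations")
  bad <- setdiff(cfg$stages, .PIPELINE_DEFAULTS$stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Run the full derivation pipeline
#'
#' Executes the requested stages in dependency order inside `out_dir`,
#' writing every intermediate artifact as plain TSV/CSV/GMT plus a JSON
#' run manifest listing the seed, thresholds, per-stage record counts and
#' an MD5 hash of every file written.  Re-running with the same
#' configuration reproduces byte-identical outputs (the manifest differs
#' only in its timestamp).  Any stage error aborts with the stage name; a
#' partial manifest flagging the failed stage is still written.
#'
#' @param cfg A `pipeline_config` from [validate_config()], or anything
#'   [validate_config()] accepts.
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) cfg <- validate_config(cfg)
  if (is.null(cfg$out_dir)) stop("config needs an out_dir")
  if (!is.null(cfg$counts_path) &&
      (!file.exists(cfg$counts_path) || !file.exists(cfg$samples_path %||% "")))
    stop("counts_path/samples_path not resolvable")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(cfg$out_dir, f)
  manifest <- list(seed = cfg$seed,
                   thresholds = cfg[c("tau_de", "tau_ifn", "pseudocount",
                                      "effect_floor", "fdr_cutoff",
                                      "n_perm")],
                   stages = list(), files = character(0),
                   status = "running")
  state <- new.env(parent = emptyenv())
  record <- function(stage, n, files) {
    manifest$stages[[stage]] <<- list(records = n, files = basename(files))
    manifest$files <<- union(manifest$files, files)
  }
  run_stage <- function(stage, fun) {
    if (!stage %in% cfg$stages) return(invisible())
    tryCatch(fun(), error = function(e) {
      manifest$status <<- paste0("failed at stage ", stage)
      manifest$error <<- conditionMessage(e)
      .write_manifest(manifest, pth("manifest.json"))
      stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  run_stage("simulate", function() {
    sim_args <- cfg$sim
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    scfg <- do.call(simulation_config, sim_args)
    state$scfg <- scfg
    state$counts <- simulate_counts(scfg)
    state$db <- simulate_annotation(scfg)
    state$array <- simulate_array(scfg)
    state$qpcr <- simulate_qpcr(scfg)
    write_count_matrix(state$counts, pth("counts.tsv"), pth("samples.tsv"))
    write_annotation_db(state$db, pth("secretome.txt"),
                        pth("interferome.tsv"), pth("secretome.gmt"))
    write_array_experiment(state$array, pth("array.csv"))
    write_ct_table(state$qpcr, pth("qpcr.tsv"))
    write_gmt(stats::setNames(list(scfg$planted_genes), "planted"),
              pth("planted.gmt"), "simulated true signature")
    record("simulate", nrow(state$counts$counts),
           pth(c("counts.tsv", "samples.tsv", "secretome.txt",
                 "interferome.tsv", "secretome.gmt", "array.csv",
                 "qpcr.tsv", "planted.gmt")))
  })

  run_stage("de", function() {
    if (is.null(state$counts)) {
      if (is.null(cfg$counts_path)) stop("no counts available")
      state$counts <- read_count_matrix(cfg$counts_path, cfg$samples_path)
    }
    filtered <- filter_low_counts(state$counts, cfg$min_cpm,
                                  cfg$min_samples)
    state$norm <- upper_quartile_normalize(filtered)
    conds <- unique(state$counts$condition_of)
    state$de <- list()
    if (all(c("P", "PTR") %in% conds))
      state$de$PTR_vs_P <- log2_fold_change(state$norm, "P", "PTR",
                                            cfg$pseudocount, cfg$tau_de)
    if (all(c("PTR", "PTR_KD") %in% conds))
      state$de$KD_vs_PTR <- log2_fold_change(state$norm, "PTR", "PTR_KD",
                                             cfg$pseudocount, cfg$tau_de)
    files <- character(0)
    for (cmp in names(state$de)) {
      f <- pth(paste0("de_", cmp, ".tsv"))
      write_de_results(state$de[[cmp]], f)
      files <- c(files, f)
    }
    state$rank <- build_rank_list(state$de$PTR_vs_P)
    write_rnk(state$rank, pth("rank_PTR_vs_P.rnk"))
    record("de", nrow(state$de$PTR_vs_P),
           c(files, pth("rank_PTR_vs_P.rnk")))
  })

  run_stage("array", function() {
    if (is.null(state$array)) stop("no array experiment available")
    conds <- unique(state$array$spots$condition)
    quant <- lapply(stats::setNames(conds, conds), function(cc)
      quantify_array(state$array, cc, cfg$detect_threshold))
    state$array_fc <- list()
    if (all(c("P", "PTR") %in% conds))
      state$array_fc$PTR_vs_P <- array_fold_changes(quant$PTR, quant$P,
                                                    cfg$array_pseudo)
    if (all(c("PTR", "PTR_KD") %in% conds))
      state$array_fc$KD_vs_PTR <- array_fold_changes(quant$PTR_KD,
                                                     quant$PTR,
                                                     cfg$array_pseudo)
    intens <- do.call(rbind, quant)
    .write_tsv(intens, pth("array_intensities.tsv"))
    files <- pth("array_intensities.tsv")
    for (cmp in names(state$array_fc)) {
      f <- pth(paste0("array_fc_", cmp, ".tsv"))
      .write_tsv(state$array_fc[[cmp]], f)
      files <- c(files, f)
    }
    record("array", nrow(intens), files)
  })

  run_stage("qpcr", function() {
    if (is.null(state$qpcr)) stop("no CT table available")
    conds <- unique(state$qpcr$condition_of)
    state$qpcr_fc <- list()
    if (all(c("P", "PTR") %in% conds))
      state$qpcr_fc$PTR_vs_P <- qpcr_fold_changes(state$qpcr, "PTR", "P",
                                                  convention =
                                                    cfg$qpcr_convention)
    if (all(c("PTR", "PTR_KD") %in% conds))
      state$qpcr_fc$KD_vs_PTR <- qpcr_fold_changes(state$qpcr, "PTR_KD",
                                                   "PTR",
                                                   convention =
                                                     cfg$qpcr_convention)
    files <- character(0)
    for (cmp in names(state$qpcr_fc)) {
      f <- pth(paste0("qpcr_fc_", cmp, ".tsv"))
      .write_tsv(state$qpcr_fc[[cmp]], f)
      files <- c(files, f)
    }
    record("qpcr", sum(vapply(state$qpcr_fc, nrow, integer(1))), files)
  })

  run_stage("derive", function() {
    if (is.null(state$de$PTR_vs_P)) stop("derivation needs the DE stage")
    if (is.null(state$db)) stop("derivation needs an annotation database")
    rules <- do.call(rule_config, cfg$rules)
    prelim <- build_preliminary_list(state$de$PTR_vs_P, state$db,
                                     cfg$tau_de, cfg$tau_ifn, "up")
    prelim_dn <- build_preliminary_list(state$de$PTR_vs_P, state$db,
                                        cfg$tau_de, cfg$tau_ifn, "down")
    ev <- assemble_evidence(de = state$de, array_fc = state$array_fc,
                            qpcr_fc = state$qpcr_fc,
                            effect_floor = cfg$effect_floor)
    state$signature <- derive_signature(ev, prelim, rules)
    state$signature_down <- derive_signature_down(ev, prelim_dn, rules)
    .write_tsv(as.data.frame(ev), pth("evidence.tsv"))
    write_signature(state$signature, pth("signature.gmt"),
                    pth("derivation_log.tsv"))
    write_signature(state$signature_down, pth("signature_down.gmt"))
    record("derive", length(state$signature$genes),
           pth(c("evidence.tsv", "signature.gmt", "derivation_log.tsv",
                 "signature_down.gmt")))
  })

  run_stage("gsea", function() {
    if (is.null(state$rank)) stop("gsea needs the DE stage")
    sets <- list()
    if (!is.null(state$signature) && length(state$signature$genes))
      sets$derived <- state$signature$genes
    if (!is.null(state$scfg)) sets$planted <- state$scfg$planted_genes
    if (!length(sets)) stop("no gene set to score")
    res <- gsea_preranked(state$rank, sets, n_perm = cfg$n_perm,
                          seed = cfg$seed, fdr_cutoff = cfg$fdr_cutoff)
    state$gsea <- res
    .write_tsv(as.data.frame(res), pth("gsea.tsv"))
    record("gsea", nrow(res), pth("gsea.tsv"))
  })

  run_stage("score", function() {
    if (is.null(state$norm)) stop("scoring needs the DE stage")
    genes <- if (!is.null(state$signature) &&
                 length(state$signature$genes)) state$signature$genes
             else if (!is.null(state$scfg)) state$scfg$planted_genes
             else stop("no gene set to score")
    sc <- average_cpm_score(state$norm, genes)
    tab <- data.frame(sample = names(sc),
                      condition = unname(state$norm$condition_of[names(sc)]),
                      score = unname(sc), stringsAsFactors = FALSE)
    .write_tsv(tab, pth("scores.tsv"))
    cmpr <- compare_scores(sc[tab$condition == "PTR"],
                           sc[tab$condition == "P"])
    state$score_test <- cmpr
    record("score", nrow(tab), pth("scores.tsv"))
  })

  manifest$status <- "ok"
  manifest$signature <- state$signature$genes
  if (!is.null(state$score_test)) manifest$score_test <- state$score_test
  .write_manifest(manifest, pth("manifest.json"))
  manifest$file_hashes <- .hash_files(manifest$files)
  invisible(manifest)
}

.hash_files <- function(files) {
  files <- files[file.exists(files)]
  h <- tools::md5sum(files)
  stats::setNames(unname(h), basename(files))
}

.write_manifest <- function(manifest, path) {
  manifest$file_hashes <- as.list(.hash_files(manifest$files))
  manifest$files <- basename(manifest$files)
  manifest$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
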