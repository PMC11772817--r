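test_that("the preliminary list is the conjunction of its three filters", {
  de <- make_de(c("A", "B", "C", "D", "E"), c(3.1, 3.1, 3.1, 1.5, -2.5))
  db <- make_db(secretome = c("A", "C", "E"), ifn_genes = c("A", "B", "E"))
  # A: DE up + secretory + IFN-regulated -> in
  # B: not secretory; C: not IFN-regulated; D: below threshold -> out
  expect_identical(build_preliminary_list(de, db), "A")
  # raising tau_DE above every |log2FC| empties the list
  expect_length(build_preliminary_list(de, db, tau_de = 5), 0)
  # the down variant mirrors the sign (E has a matching "up" record type
  # requirement? membership only needs any record at threshold)
  expect_identical(build_preliminary_list(de, db, direction = "down"), "E")
})

test_that("evidence assembly maps, derives modality, and enforces keys", {
  de <- list(PTR_vs_P = make_de(c("LCN2", "X"), c(2.5, 0.1)))
  ev <- assemble_evidence(de = de)
  # only RNA-seq provided: only rnaseq records, modality derived
  expect_setequal(unique(ev$assay), "rnaseq")
  expect_setequal(unique(ev$modality), "transcriptomic")
  expect_true(ev$significant[ev$gene == "LCN2"])
  expect_false(ev$significant[ev$gene == "X"])

  # array ratio +1.9 maps through the target map to a proteomic up record
  afc <- data.frame(target = c("Lipocalin-2", "Mystery"),
                    log2_ratio = c(1.9, 1.0), direction = "up",
                    stringsAsFactors = FALSE)
  tm <- data.frame(target = "Lipocalin-2", gene = "LCN2",
                   stringsAsFactors = FALSE)
  expect_warning(
    ev2 <- assemble_evidence(array_fc = list(PTR_vs_P = afc),
                             target_map = tm),
    "Mystery")
  expect_identical(ev2$gene, "LCN2")
  expect_identical(ev2$modality, "proteomic")
  expect_identical(ev2$direction, "up")
  expect_equal(ev2$magnitude, 1.9)

  # duplicate (gene, assay, comparison) cells are an error
  dup <- data.frame(gene = "IL6", assay = "elisa", comparison = "PTR_vs_P",
                    direction = "up", magnitude = c(1, 2),
                    significant = TRUE, stringsAsFactors = FALSE)
  expect_error(evidence_matrix(dup), "duplicate")
  # "unchanged" records can never be significant
  un <- data.frame(gene = "IL6", assay = "elisa", comparison = "PTR_vs_P",
                   direction = "unchanged", magnitude = 0,
                   significant = TRUE, stringsAsFactors = FALSE)
  expect_false(evidence_matrix(un)$significant)
})

test_that("the integration rule reproduces the five-factor worked panel", {
  wx <- ptis_worked_example()
  sig <- derive_signature(wx$evidence, wx$prelim)
  expect_identical(sig$genes, c("CCL2", "IL1RN", "IL6", "LCN2", "NOS2"))
  # the derivation log shows every step passed for every member
  dl <- sig$derivation_log
  expect_true(all(dl$selected))
  expect_true(all(dl$in_preliminary & dl$proteomic_up & dl$kd_reversed &
                    dl$cross_confirmed))
  # empty evidence gives an empty signature
  expect_length(derive_signature(wx$evidence[0, ], character(0))$genes, 0)
})

test_that("rule steps are individually toggleable and monotone", {
  wx <- ptis_worked_example()
  # drop the knockdown-reversal evidence: genes fail step 3 ...
  ev_no_kd <- evidence_matrix(
    as.data.frame(wx$evidence)[wx$evidence$comparison != "KD_vs_PTR", ])
  expect_length(derive_signature(ev_no_kd, wx$prelim)$genes, 0)
  # ... and disabling the conjunct restores the full signature
  relaxed <- rule_config(require_kd_reversal = FALSE)
  expect_length(derive_signature(ev_no_kd, wx$prelim, relaxed)$genes, 5)
  # removing any single conjunct never shrinks the signature
  full <- derive_signature(wx$evidence, wx$prelim)$genes
  for (rl in list(rule_config(require_preliminary = FALSE),
                  rule_config(require_proteomic = FALSE),
                  rule_config(require_kd_reversal = FALSE),
                  rule_config(confirmation = "none"))) {
    expect_true(all(full %in% derive_signature(wx$evidence, wx$prelim,
                                               rl)$genes))
  }
  # adding evidence rows never removes a member that already passed
  extra <- data.frame(gene = "IL6", assay = "western",
                      comparison = "PTR_vs_P", direction = "up",
                      magnitude = 1, significant = TRUE,
                      stringsAsFactors = FALSE)
  base_cols <- c("gene", "assay", "comparison", "direction", "magnitude",
                 "significant")
  grown <- evidence_matrix(rbind(as.data.frame(wx$evidence)[, base_cols],
                                 extra))
  expect_true(all(full %in% derive_signature(grown, wx$prelim)$genes))
  # strict proteomic-only knockdown mode still passes (array covers it)
  strict <- rule_config(kd_modality = "proteomic")
  expect_length(derive_signature(wx$evidence, wx$prelim, strict)$genes, 5)
  # cross-modality confirmation is required by default
  transcript_only <- evidence_matrix(as.data.frame(
    wx$evidence)[wx$evidence$modality == "transcriptomic" |
                   wx$evidence$comparison == "KD_vs_PTR", ])
  expect_length(derive_signature(transcript_only, wx$prelim)$genes, 0)
})

test_that("the down derivation is the exact mirror of the up derivation", {
  wx <- ptis_worked_example()
  flipped <- as.data.frame(wx$evidence)
  flipped$magnitude <- -flipped$magnitude
  flipped$direction <- c(up = "down", down = "up",
                         unchanged = "unchanged")[flipped$direction]
  down <- derive_signature_down(evidence_matrix(flipped), wx$prelim)
  expect_identical(down$genes, derive_signature(wx$evidence, wx$prelim)$genes)
  # a down transcript without proteomic confirmation is excluded
  solo <- evidence_matrix(data.frame(
    gene = "G", assay = "rnaseq", comparison = "PTR_vs_P",
    direction = "down", magnitude = -2.5, significant = TRUE,
    stringsAsFactors = FALSE))
  expect_length(derive_signature_down(solo, "G")$genes, 0)
  # up- and down-signatures from one evidence matrix are disjoint
  for (s in 1:5) {
    set.seed(s)
    genes <- sprintf("r%02d", 1:12)
    mag <- rnorm(36, 0, 2)
    ev <- evidence_matrix(data.frame(
      gene = rep(genes, 3),
      assay = rep(c("rnaseq", "array", "qrtpcr"), each = 12),
      comparison = sample(c("PTR_vs_P", "KD_vs_PTR"), 36, replace = TRUE),
      direction = ifelse(abs(mag) < 0.58, "unchanged",
                         ifelse(mag > 0, "up", "down")),
      magnitude = mag, significant = abs(mag) >= 0.58,
      stringsAsFactors = FALSE))
    up <- derive_signature(ev, genes, rule_config(confirmation = "none"))
    dn <- derive_signature_down(ev, genes, rule_config(confirmation = "none"))
    expect_length(intersect(up$genes, dn$genes), 0)
  }
})

test_that("a full synthetic panel recovers planted genes without false hits", {
  out <- file.path(tempdir(), "sig-recovery")
  cfg <- validate_config(list(
    out_dir = out, seed = 42,
    stages = c("simulate", "de", "array", "qpcr", "derive")))
  man <- run_pipeline(cfg)
  planted <- simulation_config(seed = 42)$planted_genes
  expect_length(setdiff(man$signature, planted), 0)
  expect_gte(length(intersect(man$signature, planted)) / length(planted),
             0.85)
})
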