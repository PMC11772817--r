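test_that("every generator is a pure function of (config, seed)", {
  cfg <- simulation_config(n_genes = 120, planted_genes = 8,
                           n_per_group = 2, seed = 11)
  cfg2 <- simulation_config(n_genes = 120, planted_genes = 8,
                            n_per_group = 2, seed = 12)
  for (gen in list(simulate_counts, simulate_annotation, simulate_array,
                   simulate_qpcr)) {
    a <- gen(cfg); b <- gen(cfg); c <- gen(cfg2)
    expect_identical(a, b)
    expect_false(identical(a, c))
  }
})

test_that("planted effects are recovered and null effects calibrated", {
  # effect-size recovery at n_per_group = 10
  cfg <- simulation_config(n_per_group = 10, seed = 3)
  ne <- upper_quartile_normalize(simulate_counts(cfg))
  de <- log2_fold_change(ne, "P", "PTR")
  m <- mean(de$log2fc[match(cfg$planted_genes, de$gene_id)])
  expect_lt(abs(m - 3), 0.3)

  # zero-effect symmetry at large n
  cfgz <- simulation_config(n_genes = 300, planted_genes = 20,
                            planted_log2fc = 0, n_per_group = 50, seed = 5)
  nez <- upper_quartile_normalize(simulate_counts(cfgz))
  dez <- log2_fold_change(nez, "P", "PTR")
  mz <- mean(dez$log2fc[match(cfgz$planted_genes, dez$gene_id)])
  expect_lt(abs(mz), 0.2)

  # null calibration: few planted genes reach |log2FC| >= 2 at n = 5
  cfg0 <- simulation_config(planted_log2fc = 0, n_per_group = 5, seed = 4)
  ne0 <- upper_quartile_normalize(simulate_counts(cfg0))
  de0 <- log2_fold_change(ne0, "P", "PTR")
  f0 <- mean(abs(de0$log2fc[match(cfg0$planted_genes, de0$gene_id)]) >= 2)
  expect_lt(f0, 0.05)

  # knockdown reversal removes the planted effect in PTR_KD vs P_KD
  cfgk <- simulation_config(n_per_group = 10, kd_reversal = 1, seed = 6)
  nek <- upper_quartile_normalize(simulate_counts(cfgk))
  dek <- log2_fold_change(nek, "P_KD", "PTR_KD")
  expect_lt(abs(mean(dek$log2fc[match(cfgk$planted_genes, dek$gene_id)])),
            0.3)
})

test_that("annotation database honors construction invariants", {
  # secretome size forced by rounding
  cfg <- simulation_config(n_genes = 10, planted_genes = 2,
                           secretome_fraction = 0.5, seed = 1)
  db <- simulate_annotation(cfg)
  expect_length(db$secretome, 5)

  # planted genes are secretory and type-I up at the 1.5 threshold
  cfg <- simulation_config(n_genes = 400, planted_genes = 25, seed = 2)
  db <- simulate_annotation(cfg)
  expect_true(all(annotate_secretome(cfg$planted_genes, db)))
  expect_true(all(is_ifn_regulated(cfg$planted_genes, db, 1.5,
                                   type = "I", direction = "up")))
  expect_true(all(db$interferome$fold_change > 0))

  # non-planted type-I-up rate within the binomial 99% CI of ifn_fraction
  cfg <- simulation_config(n_genes = 5000, planted_genes = 50,
                           ifn_fraction = 0.3, seed = 7)
  db <- simulate_annotation(cfg)
  non_planted <- setdiff(cfg$universe, cfg$planted_genes)
  hits <- sum(is_ifn_regulated(non_planted, db, 1.5, type = "I",
                               direction = "up"))
  ci <- qbinom(c(0.005, 0.995), length(non_planted), 0.3)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})

test_that("array volumes scale with exposure and sit above background", {
  cfg <- simulation_config(n_genes = 100, planted_genes = 10,
                           array_targets_extra = 10, seed = 9)
  x <- simulate_array(cfg)
  sp <- x$spots
  expect_gte(length(unique(sp$exposure_s)), 2)
  ex <- sort(unique(sp$exposure_s))[1:2]
  # signal spots: exposure ratio equals the exposure gain exactly
  # (per-spot noise is shared across re-exposures of one membrane)
  key <- function(d) paste(d$membrane, d$row, d$col)
  s1 <- sp[sp$exposure_s == ex[1] & sp$spot_class == "target", ]
  s2 <- sp[sp$exposure_s == ex[2] & sp$spot_class == "target", ]
  s2 <- s2[match(key(s1), key(s2)), ]
  unsat <- s2$volume < x$saturation_ceiling
  expect_true(any(unsat))
  expect_equal(s2$volume[unsat] / s1$volume[unsat],
               rep(ex[2] / ex[1], sum(unsat)))
  # background below every planted-target spot mean on PTR membranes
  for (s in 1:20) {
    xi <- simulate_array(simulation_config(n_genes = 50, planted_genes = 5,
                                           array_targets_extra = 5,
                                           seed = s))
    spi <- xi$spots
    ptr <- spi[spi$condition == "PTR" & spi$exposure_s ==
                 min(spi$exposure_s), ]
    bg <- mean(ptr$volume[ptr$spot_class == "background"])
    planted_means <- vapply(
      simulation_config(n_genes = 50, planted_genes = 5, seed = s)$planted_genes,
      function(tg) mean(ptr$volume[!is.na(ptr$target) & ptr$target == tg]),
      numeric(1))
    expect_true(all(bg < planted_means))
  }
})

test_that("noiseless qPCR tables encode the planted shift exactly", {
  cfg <- simulation_config(n_genes = 60, planted_genes = 5, n_per_group = 2,
                           qpcr_noise_sd = 0, seed = 13)
  t <- simulate_qpcr(cfg)
  g <- cfg$planted_genes[1]
  ct_p <- t$ct$ct[t$ct$gene == g & t$ct$sample == "P_1"]
  ct_ptr <- t$ct$ct[t$ct$gene == g & t$ct$sample == "PTR_1"]
  expect_equal(ct_ptr, ct_p - 3)

  # housekeeping CTs stay within the configured noise budget
  vars <- vapply(1:10, function(s) {
    ti <- simulate_qpcr(simulation_config(n_genes = 60, planted_genes = 5,
                                          qpcr_noise_sd = 0.15, seed = s))
    max(vapply(ti$housekeeping_genes, function(h)
      var(ti$ct$ct[ti$ct$gene == h]), numeric(1)))
  }, numeric(1))
  expect_lt(mean(vars), 2 * 0.15^2)
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(simulation_config(conditions = c("P", "XXX")),
               "unknown condition")
  expect_error(simulation_config(n_genes = 10, planted_genes = "absent"),
               "outside the simulated gene universe")
  expect_error(simulation_config(secretome_fraction = 1.2), "fractions")
  expect_error(simulation_config(nb_dispersion = 0), "dispersion")
  expect_error(simulation_config(kd_reversal = 2), "kd_reversal")
})
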