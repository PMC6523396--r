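test_that("replicate agreement splits shared, discordant and one-library sites", {
  sites <- sprintf("s%03d", 1:100)
  a <- setNames(rep("1/1", 100), sites)
  ra <- replicate_agreement(a, a)
  expect_equal(ra$agreed, 100)
  expect_equal(ra$disagreed, 0)
  expect_equal(ra$rate, 100)

  b <- a
  b[1:5] <- "0/1"
  ra2 <- replicate_agreement(a, b)
  expect_equal(ra2$agreed, 95)
  expect_equal(ra2$disagreed, 5)
  expect_equal(ra2$rate, 95)
  # symmetric in its arguments
  ra2r <- replicate_agreement(b, a)
  expect_equal(ra2$agreed, ra2r$agreed)
  expect_equal(ra2$rate, ra2r$rate)

  disjoint1 <- setNames(c("1/1", NA), c("x", "y"))
  disjoint2 <- setNames(c(NA, "1/1"), c("x", "y"))
  ra3 <- replicate_agreement(disjoint1, disjoint2)
  expect_equal(ra3$one_library_only, 2)
  expect_false(ra3$rate_defined)
  expect_true(is.na(ra3$rate))
})

test_that("planted replicate discordance is recovered within its binomial CI", {
  cfg <- sim_config(seed = 29, n_chrom = 2, chrom_len = 1000000L,
                    n_loci = 60, locus_len_range = c(8000, 15000),
                    n_strains = 8, n_replicate_strains = 2,
                    n_clean = 2200, n_singletons = 0, n_close_pairs = 0,
                    n_multiallelic = 0, het_rate = 0, missing_rate = 0,
                    replicate_discordance_rate = 0.05)
  sim <- simulate_genome(cfg)
  loci <- simulate_annotation(cfg, sim)
  truth <- simulate_strain_vcf(cfg, sim, loci)
  key <- paste(truth$variants$chrom, truth$variants$pos)
  ra <- replicate_agreement(setNames(truth$lib_calls[, "S01_L1"], key),
                            setNames(truth$lib_calls[, "S01_L2"], key))
  n <- ra$agreed + ra$disagreed
  expect_gte(n, 2000)
  ci <- 100 * (1 - binom.test(ra$disagreed, n, p = 0.05)$conf.int)
  expect_gte(95, min(ci))
  expect_lte(95, max(ci))
})

test_that("depth gate retains exactly the at-least-100x markers", {
  panel <- data.frame(marker_id = c("a", "b", "c"),
                      mean_depth = c(99, 100, 366750))
  expect_equal(depth_gate(panel)$marker_id, c("b", "c"))
  n <- 384
  panel2 <- data.frame(marker_id = sprintf("m%03d", 1:n),
                       mean_depth = c(rep(35, 11), rep(150, n - 11)))
  expect_equal(nrow(depth_gate(panel2)), 373)
  expect_equal(nrow(depth_gate(panel2[0, , drop = FALSE])), 0)
})

test_that("panel mean depth averages per-marker call depths", {
  calls <- data.frame(marker_id = c("a", "a", "b"),
                      strain_id = c("s1", "s2", "s1"),
                      genotype = "A/A", depth = c(80, 120, 500))
  panel <- panel_mean_depth(data.frame(marker_id = c("a", "b")), calls)
  expect_equal(panel$mean_depth, c(100, 500))
})

test_that("per-strain concordance reproduces published count-to-rate rows", {
  r1 <- concordance_row("Kashimamugi", 191, 19, 7, 5, 131)
  expect_equal(r1$rate_total, 94.595)
  expect_equal(r1$rate_snp, 96.465)
  expect_equal(r1$rate_indel, 79.167)
  r2 <- concordance_row("Tochinoibuki", 133, 16, 80, 27, 97)
  expect_equal(r2$rate_total, 58.203)
  zero <- concordance_row("none", 0, 0, 0, 0, 10)
  expect_true(is.na(zero$rate_total))
})

test_that("strain concordance classifies markers and flags off-panel calls", {
  panel <- data.frame(marker_id = c("m1", "m2", "m3", "m4"),
                      vtype = c("SNP", "SNP", "INDEL", "SNP"))
  rna <- setNames(c("A/A", "T/T", "A/AT", NA), panel$marker_id)
  amp <- setNames(c("A/A", "C/C", "A/A", "G/G"), panel$marker_id)
  row <- strain_concordance(rna, amp, panel, "sX")
  expect_equal(row$true_snp, 1)
  expect_equal(row$false_snp, 1)
  expect_equal(row$false_indel, 1)  # het insertion vs hom ref
  expect_equal(row$not_detected, 1)
  expect_equal(row$missing_rnaseq, 1)
  stray <- c(rna, setNames("A/A", "m99"))
  expect_warning(strain_concordance(stray, amp, panel, "sX"), "m99")
})

test_that("indel genotype normalization tolerates anchor representation", {
  # insertion called with and without a shared anchor base
  expect_equal(transgeno:::normalize_gt("A/AT"),
               transgeno:::normalize_gt("AT/A"))
  expect_equal(transgeno:::normalize_gt("CA/CAT"),
               transgeno:::normalize_gt("A/AT"))
  expect_equal(transgeno:::normalize_gt("a/t"), "A/T")
  expect_true(is.na(transgeno:::normalize_gt(".")))
})

test_that("summary statistics over the packaged strain table are exact", {
  t2 <- table2_counts()
  expect_equal(nrow(t2), 38)
  rows <- do.call(rbind, lapply(seq_len(nrow(t2)), function(i) {
    concordance_row(t2$strain_id[i], t2$true_snp[i], t2$true_indel[i],
                    t2$false_snp[i], t2$false_indel[i], t2$not_detected[i])
  }))
  # every stored rate cell reproduces from the counts (3-decimal rendering)
  expect_equal(rows$rate_total, t2$rate_total)
  expect_equal(rows$rate_snp, t2$rate_snp)
  expect_equal(rows$rate_indel, t2$rate_indel)
  s <- summarize_concordance(rows, threshold = 90)
  expect_equal(s$n_at_least_threshold, 34)
  expect_equal(round_half_up(s$mean_rate_snp, 1), 93.1)
  expect_equal(round_half_up(s$mean_rate_indel, 1), 65.1)
  expect_equal(round_half_up(s$min_rate_total, 1), 58.2)
  expect_equal(round_half_up(s$max_rate_total, 1), 94.6)
})

test_that("single-row summary degenerates correctly", {
  row <- concordance_row("only", 10, 2, 1, 1, 0)
  s <- summarize_concordance(row, threshold = 90)
  expect_equal(s$n_strains, 1)
  expect_equal(s$mean_rate_snp, row$rate_snp)
  expect_true(s$n_at_least_threshold %in% c(0, 1))
})

test_that("marker aggregation counts missing, complete and <5-mismatch markers", {
  strains <- c("s1", "s2", "s3")
  markers <- sprintf("m%02d", 1:6)
  rna <- matrix("A/A", 6, 3, dimnames = list(markers, strains))
  amp <- rna
  amp["m02", "s1"] <- "T/T"                     # 1 mismatch
  amp["m03", ] <- "T/T"                          # 3 mismatches
  rna["m04", "s2"] <- NA                         # missing data
  amp["m05", "s3"] <- NA                         # missing data
  amp["m06", "s1"] <- "T/T"; rna["m06", "s2"] <- NA  # mismatch + missing
  ms <- marker_summary(rna, amp)
  expect_equal(ms$n_markers, 6)
  expect_equal(ms$n_missing_data, 3)
  expect_equal(ms$n_complete_match, 3)  # m01, m04, m05
  expect_equal(ms$n_lt5_mismatch, 3)    # m02, m03, m06
})

test_that("noise-free amplicon simulation gives perfect concordance", {
  cfg <- sim_config(seed = 41, het_rate = 0, missing_rate = 0,
                    replicate_discordance_rate = 0,
                    amplicon_error_rate = 0, amplicon_missing_rate = 0)
  b <- simulate_bundle(cfg, tempfile("amp0"))
  res <- run_cascade(b$paths$vcf, b$truth$metadata)
  panel <- panel_mean_depth(b$amplicon$panel[, 1:4], b$amplicon$calls)
  gated <- depth_gate(panel)
  for (s in c("S01", "S05")) {
    row <- strain_concordance(rnaseq_panel_calls(res$matrix, gated, s),
                              amplicon_panel_calls(b$amplicon$calls, s, gated),
                              gated, s)
    expect_equal(row$rate_total, 100)
    expect_equal(row$not_detected, 0)
  }
})

test_that("planted amplicon error rate is recovered within its binomial CI", {
  cfg <- sim_config(seed = 43, n_strains = 20, n_clean = 120,
                    amplicon_n_markers = 120, het_rate = 0, missing_rate = 0,
                    replicate_discordance_rate = 0,
                    amplicon_error_rate = 0.1, amplicon_missing_rate = 0,
                    amplicon_frac_low_depth = 0)
  sim <- simulate_genome(cfg)
  loci <- simulate_annotation(cfg, sim)
  truth <- simulate_strain_vcf(cfg, sim, loci)
  amp <- simulate_amplicon(cfg, truth)
  panel <- panel_mean_depth(amp$panel[, 1:4], amp$calls)
  gated <- depth_gate(panel)
  # truth genotypes on the RNA-Seq side, noisy amplicon on the other
  mism <- 0; tot <- 0
  for (s in truth$strains) {
    rna <- setNames(amp$true_calls[gated$marker_id, s], gated$marker_id)
    obs <- amplicon_panel_calls(amp$calls, s, gated)
    row <- strain_concordance(rna, obs, gated, s)
    mism <- mism + row$false_snp + row$false_indel
    tot <- tot + row$true_snp + row$true_indel + row$false_snp +
      row$false_indel
  }
  ci <- binom.test(mism, tot, p = 0.1)$conf.int
  expect_gte(0.1, ci[1])
  expect_lte(0.1, ci[2])
})
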