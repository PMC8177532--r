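test_that("maternal homozygous loci are found exactly", {
  g <- as_geno_tbl(data.frame(
    sample_id = rep(c("mom", "kid"), each = 3),
    locus_id = rep(c("L1", "L2", "L3"), 2),
    allele_1 = c(1L, 1L, NA, 2L, 1L, 1L),
    allele_2 = c(1L, 2L, NA, 2L, 1L, 2L)
  ))
  expect_equal(find_maternal_homozygous_loci(g, "mom"), "L1")
  expect_error(find_maternal_homozygous_loci(g, "nobody"), "not found")

  # fully heterozygous mother: empty subset, scan degenerates gracefully
  g2 <- as_geno_tbl(data.frame(
    sample_id = rep(c("mom", "kid"), each = 2),
    locus_id = rep(c("L1", "L2"), 2),
    allele_1 = 1L, allele_2 = 2L
  ))
  expect_length(find_maternal_homozygous_loci(g2, "mom"), 0)
  w <- capture_warnings(sc <- scan_paternal_alleles(g2, "mom"))
  expect_match(w, "homozygous at no locus", all = FALSE)
  expect_equal(sc$conservative_count, 0)
  expect_equal(sc$liberal_count, 0)

  # HWE mother at p = 0.5: about half the loci are homozygous
  cfg <- litter_sim_config(n_loci = 10000, allele_freq = 0.5, seed = 21)
  par <- simulate_parents(cfg)
  g3 <- as_geno_tbl(data.frame(
    sample_id = "mother", locus_id = par$mother$locus_id,
    allele_1 = par$mother$allele_1, allele_2 = par$mother$allele_2
  ))
  n_hom <- length(find_maternal_homozygous_loci(g3, "mother"))
  expect_lt(abs(n_hom / 10000 - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("scan equals the naive triple-loop recomputation cell for cell", {
  for (seed in 1:6) {
    g <- random_geno(
      n_samples = sample(3:8, 1), n_loci = sample(20:60, 1),
      missing = 0.25, seed = seed
    )
    kids <- setdiff(geno_samples(g), "mother")
    for (policy in c("strict", "evaluated_only")) {
      sc <- suppressWarnings(
        scan_paternal_alleles(g, "mother", kids, missing_policy = policy)
      )
      orc <- oracle_scan(g, "mother", kids, policy)
      expect_identical(sc$loci, orc$hom)
      expect_identical(sc$flags, orc$flags[, sc$loci, drop = FALSE])
      expect_identical(sc$conservative_count, orc$conservative)
      expect_identical(sc$liberal_count, as.integer(orc$liberal))
    }
  }
})

test_that("scan counts obey their structural invariants", {
  g <- random_geno(8, 80, missing = 0.15, seed = 31)
  kids <- setdiff(geno_samples(g), "mother")
  sc <- suppressWarnings(scan_paternal_alleles(g, "mother", kids))
  expect_lte(sc$conservative_count, sc$liberal_count)
  expect_lte(sc$liberal_count, length(sc$loci))
  expect_true(all(stats::na.omit(sc$per_offspring$paternal_fraction) >= 0))
  expect_true(all(stats::na.omit(sc$per_offspring$paternal_fraction) <= 1))

  # dropping an offspring never decreases the conservative count
  for (drop in kids[1:3]) {
    sc_sub <- suppressWarnings(
      scan_paternal_alleles(g, "mother", setdiff(kids, drop))
    )
    expect_gte(sc_sub$conservative_count, sc$conservative_count)
  }
})

test_that("missing-data policies differ exactly on loci with missing calls", {
  # mother A/A at two loci; kid1 flagged at both; kid2 missing at L2
  g <- as_geno_tbl(data.frame(
    sample_id = rep(c("mom", "kid1", "kid2"), each = 2),
    locus_id = rep(c("L1", "L2"), 3),
    allele_1 = c(1L, 1L, 2L, 1L, 2L, NA),
    allele_2 = c(1L, 1L, 2L, 2L, 2L, NA)
  ))
  strict <- scan_paternal_alleles(g, "mom", c("kid1", "kid2"))
  eval_only <- scan_paternal_alleles(
    g, "mom", c("kid1", "kid2"), missing_policy = "evaluated_only"
  )
  expect_equal(strict$conservative_loci, "L1")
  expect_equal(eval_only$conservative_loci, c("L1", "L2"))
})

test_that("trivial scans are forced", {
  # everyone identical to the homozygous mother: zero counts
  g <- as_geno_tbl(data.frame(
    sample_id = rep(c("mom", "k1", "k2"), each = 4),
    locus_id = rep(sprintf("L%d", 1:4), 3),
    allele_1 = 1L, allele_2 = 1L
  ))
  sc <- scan_paternal_alleles(g, "mom")
  expect_equal(sc$conservative_count, 0L)
  expect_equal(sc$liberal_count, 0L)
  expect_equal(sc$per_offspring$paternal_fraction, c(0, 0))
})

test_that("heterozygosity is computed per sample with NA for uncallable", {
  g <- as_geno_tbl(data.frame(
    sample_id = rep(c("homo", "hetero", "empty"), each = 2),
    locus_id = rep(c("L1", "L2"), 3),
    allele_1 = c(1L, 2L, 1L, 1L, NA, NA),
    allele_2 = c(1L, 2L, 2L, 2L, NA, NA)
  ))
  expect_warning(h <- offspring_heterozygosity(g), "zero non-missing")
  expect_equal(h$heterozygosity, c(0, 1, NA))

  # HWE individual at p = 0.5 has heterozygosity ~ 0.5
  cfg <- litter_sim_config(n_loci = 10000, allele_freq = 0.5, seed = 22)
  mom <- simulate_parents(cfg)$mother
  g2 <- as_geno_tbl(data.frame(
    sample_id = "m", locus_id = mom$locus_id,
    allele_1 = mom$allele_1, allele_2 = mom$allele_2
  ))
  expect_lt(abs(offspring_heterozygosity(g2)$heterozygosity - 0.5),
    3 * sqrt(0.25 / 10000)
  )
})

test_that("classifier calls forced litters and respects thresholds", {
  # zero-error gametic duplication: every offspring parthenogen, litter FP
  cfg <- litter_sim_config(
    n_loci = 300, n_offspring = 4, mode = "fp_gametic_duplication",
    dropout_rate = 0, miscall_rate = 0, missing_rate = 0, seed = 41
  )
  sim <- simulate_litter(cfg)
  sc <- scan_paternal_alleles(sim$genotypes, "mother")
  mc <- classify_mode(sc, offspring_heterozygosity(sim$genotypes), sim$meta)
  expect_equal(mc$litter_call, "FP")
  expect_true(all(mc$calls$call == "parthenogen"))
  expect_true(mc$all_male)

  # zero-error Mendelian litter with an informative sire: litter LTSS
  cfg2 <- litter_sim_config(
    n_loci = 300, n_offspring = 4, mode = "ltss", allele_freq = c(0.3, 0.7),
    dropout_rate = 0, miscall_rate = 0, missing_rate = 0, seed = 42
  )
  sim2 <- simulate_litter(cfg2)
  sc2 <- scan_paternal_alleles(sim2$genotypes, "mother")
  mc2 <- classify_mode(sc2, offspring_heterozygosity(sim2$genotypes), sim2$meta)
  expect_equal(mc2$litter_call, "LTSS")
  expect_true(all(mc2$calls$call == "sexual"))

  expect_error(mode_thresholds(sexual_min = 0.01, parthenogen_max = 0.05),
    "below"
  )
})

test_that("a mixed litter recovers per-offspring labels at default error rates", {
  # 3 sexual + 2 parthenogen offspring of the same mother
  cfg_s <- litter_sim_config(
    n_loci = 500, n_offspring = 3, mode = "ltss", seed = 43
  )
  par <- simulate_parents(cfg_s)
  sexual <- simulate_ltss_litter(cfg_s, par$mother, par$sires)
  cfg_p <- litter_sim_config(
    n_loci = 500, n_offspring = 2, mode = "fp_terminal_fusion", seed = 44
  )
  parth <- simulate_fp_litter(cfg_p, par$mother)
  pg <- parth$genotypes[parth$genotypes$sample_id != "mother", ]
  pg$sample_id <- sub("^off", "fp", pg$sample_id)
  combined <- as_geno_tbl(rbind(
    as.data.frame(sexual$genotypes), as.data.frame(pg)
  ))
  combined <- apply_genotyping_error(
    combined,
    dropout_rate = cfg_s$dropout_rate, miscall_rate = cfg_s$miscall_rate,
    seed = 45
  )
  sc <- scan_paternal_alleles(combined, "mother")
  mc <- classify_mode(sc, offspring_heterozygosity(combined))
  calls <- setNames(mc$calls$call, mc$calls$sample_id)
  expect_true(all(calls[c("off_01", "off_02", "off_03")] == "sexual"))
  expect_true(all(calls[c("fp_01", "fp_02")] == "parthenogen"))
  expect_equal(mc$litter_call, "LTSS")
})
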