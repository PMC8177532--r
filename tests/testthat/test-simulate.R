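test_that("configuration validation rejects bad inputs", {
  expect_error(litter_sim_config(n_loci = -1), "n_loci")
  expect_error(litter_sim_config(dropout_rate = 1.5), "probability")
  expect_error(litter_sim_config(allele_freq = c(0.9, 0.1)), "a <= b")
  expect_error(
    litter_sim_config(mode = "fp_terminal_fusion", n_sires = 2),
    "n_sires"
  )
  expect_error(litter_sim_config(mode = "ltss", n_sires = 0), "n_sires")
  expect_error(
    litter_sim_config(n_offspring = 3, sire_assignment = c(1L, 2L)),
    "sire_assignment"
  )
})

test_that("same seed and config reproduce the simulation byte for byte", {
  cfg <- litter_sim_config(
    n_loci = 80, n_offspring = 4, missing_rate = 0.1, seed = 123
  )
  s1 <- simulate_litter(cfg)
  s2 <- simulate_litter(cfg)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$truth$sire_of, s2$truth$sire_of)
  # and a different seed changes it
  cfg2 <- litter_sim_config(
    n_loci = 80, n_offspring = 4, missing_rate = 0.1, seed = 124
  )
  expect_false(identical(simulate_litter(cfg2)$genotypes, s1$genotypes))
})

test_that("parent draws follow Hardy-Weinberg expectations", {
  # fixed frequency 1: mother homozygous reference everywhere
  cfg <- litter_sim_config(n_loci = 50, allele_freq = 1, seed = 1)
  par <- simulate_parents(cfg)
  expect_true(all(par$mother$allele_1 == 1L & par$mother$allele_2 == 1L))

  # p = 0.5: heterozygosity ~ 2pq = 0.5 within 3 binomial SEs
  cfg <- litter_sim_config(n_loci = 10000, allele_freq = 0.5, seed = 2)
  mom <- simulate_parents(cfg)$mother
  het <- mean(mom$allele_1 != mom$allele_2)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.5 * 0.5 / 10000))
})

test_that("Mendelian litters obey transmission expectations", {
  # mother A/A, sire B/B: every offspring A/B at every locus
  cfg <- litter_sim_config(
    n_loci = 100, n_offspring = 3, mode = "ltss", seed = 3,
    dropout_rate = 0, miscall_rate = 0, missing_rate = 0
  )
  lit <- simulate_ltss_litter(
    cfg, const_parent(100, 1L, 1L), list(const_parent(100, 2L, 2L))
  )
  kids <- lit$genotypes[lit$genotypes$sample_id != "mother", ]
  expect_true(all(kids$allele_1 == 1L & kids$allele_2 == 2L))

  # mother A/A, sire A/B: offspring carries B at ~half the loci
  cfg1 <- litter_sim_config(
    n_loci = 10000, n_offspring = 1, mode = "ltss", seed = 4
  )
  lit <- simulate_ltss_litter(
    cfg1, const_parent(10000, 1L, 1L), list(const_parent(10000, 1L, 2L))
  )
  kid <- lit$genotypes[lit$genotypes$sample_id != "mother", ]
  frac_b <- mean(kid$allele_2 == 2L)
  expect_lt(abs(frac_b - 0.5), 3 * sqrt(0.25 / 10000))

  # mother A/B x sire A/B: 1/4 AA, 1/2 AB, 1/4 BB across loci
  lit <- simulate_ltss_litter(
    cfg1, const_parent(10000, 1L, 2L), list(const_parent(10000, 1L, 2L))
  )
  kid <- lit$genotypes[lit$genotypes$sample_id != "mother", ]
  p_aa <- mean(kid$allele_1 == 1L & kid$allele_2 == 1L)
  p_ab <- mean(kid$allele_1 == 1L & kid$allele_2 == 2L)
  expect_lt(abs(p_aa - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
  expect_lt(abs(p_ab - 0.5), 3 * sqrt(0.5 * 0.5 / 10000))

  # sire index out of range
  cfg_bad <- litter_sim_config(
    n_loci = 10, n_offspring = 2, mode = "ltss", n_sires = 2,
    sire_assignment = c(1L, 3L), seed = 1
  )
  expect_error(
    simulate_ltss_litter(cfg_bad, const_parent(10, 1L, 1L),
      list(const_parent(10, 1L, 2L), const_parent(10, 2L, 2L))[1:2]
    ),
    "out of range"
  )
})

test_that("automictic litters carry only maternal alleles", {
  for (mode in c(
    "fp_terminal_fusion", "fp_central_fusion", "fp_gametic_duplication"
  )) {
    cfg <- litter_sim_config(
      n_loci = 300, n_offspring = 4, mode = mode, seed = 8,
      dropout_rate = 0, miscall_rate = 0, missing_rate = 0
    )
    par <- simulate_parents(cfg)
    lit <- simulate_fp_litter(cfg, par$mother)
    m <- sirescan:::as_geno_matrices(lit$genotypes)
    for (kid in setdiff(m$samples, "mother")) {
      ok <- (m$a1[kid, ] == m$a1["mother", ] | m$a1[kid, ] == m$a2["mother", ]) &
        (m$a2[kid, ] == m$a1["mother", ] | m$a2[kid, ] == m$a2["mother", ])
      expect_true(all(ok))
    }
    expect_true(all(lit$meta$sex[lit$meta$role == "offspring"] == "male"))
  }
})

test_that("automixis heterozygosity follows the retention parameter", {
  # gametic duplication: heterozygosity exactly 0 before error overlay
  cfg <- litter_sim_config(
    n_loci = 200, n_offspring = 2, mode = "fp_gametic_duplication", seed = 10
  )
  lit <- simulate_fp_litter(cfg, simulate_parents(cfg)$mother)
  kids <- lit$genotypes[lit$genotypes$sample_id != "mother", ]
  expect_true(all(kids$allele_1 == kids$allele_2))

  # het_retention = 1: offspring identical to mother
  cfg <- litter_sim_config(
    n_loci = 200, n_offspring = 1, mode = "fp_central_fusion",
    het_retention = 1, seed = 11
  )
  mom <- simulate_parents(cfg)$mother
  lit <- simulate_fp_litter(cfg, mom)
  kid <- lit$genotypes[lit$genotypes$sample_id != "mother", ]
  expect_equal(kid$allele_1, mom$allele_1)
  expect_equal(kid$allele_2, mom$allele_2)

  # het_retention = 0.3 on a 50%-heterozygous mother: offspring het ~ 0.15
  cfg <- litter_sim_config(
    n_loci = 10000, n_offspring = 1, mode = "fp_terminal_fusion",
    allele_freq = 0.5, het_retention = 0.3, seed = 12
  )
  mom <- simulate_parents(cfg)$mother
  lit <- simulate_fp_litter(cfg, mom)
  kid <- lit$genotypes[lit$genotypes$sample_id != "mother", ]
  mom_het <- mean(mom$allele_1 != mom$allele_2)
  kid_het <- mean(kid$allele_1 != kid$allele_2)
  expected <- 0.3 * mom_het
  expect_lt(abs(kid_het - expected), 3 * sqrt(expected * (1 - expected) / 10000))
})

test_that("error overlay identity, saturation and dropout expectation", {
  g <- random_geno(4, 50, missing = 0.1, seed = 13)
  expect_identical(as.data.frame(apply_genotyping_error(g)), as.data.frame(g))
  all_miss <- apply_genotyping_error(g, missing_rate = 1, seed = 1)
  expect_true(all(is.na(all_miss$allele_1)))

  # all-heterozygous matrix, dropout 0.2: ~80% of cells stay heterozygous
  het <- as_geno_tbl(data.frame(
    sample_id = rep(sprintf("s%d", 1:5), each = 2000),
    locus_id = rep(sprintf("L%04d", 1:2000), 5),
    allele_1 = 1L, allele_2 = 2L
  ))
  noisy <- apply_genotyping_error(het, dropout_rate = 0.2, seed = 14)
  frac_het <- mean(noisy$allele_1 != noisy$allele_2)
  expect_lt(abs(frac_het - 0.8), 3 * sqrt(0.2 * 0.8 / 10000))
  # dropped cells became one of the two original homozygotes
  dropped <- noisy[noisy$allele_1 == noisy$allele_2, ]
  expect_true(all(dropped$allele_1 %in% c(1L, 2L)))
})

test_that("error overlay commutes with sample reordering", {
  g <- random_geno(5, 40, missing = 0, seed = 15)
  shuffled <- as_geno_tbl(g[sample(nrow(g)), ])
  a <- apply_genotyping_error(
    g, dropout_rate = 0.2, miscall_rate = 0.2, missing_rate = 0.2, seed = 99
  )
  b <- apply_genotyping_error(
    shuffled, dropout_rate = 0.2, miscall_rate = 0.2, missing_rate = 0.2,
    seed = 99
  )
  key <- function(x) {
    x <- as.data.frame(x)
    x[order(x$sample_id, x$locus_id), , drop = FALSE]
  }
  expect_equal(key(a), key(b), ignore_attr = TRUE)
})

test_that("stage seeds are decorrelated within one configuration", {
  # parental allele-frequency draws must not be reused as transmission
  # draws: with one shared stream the two stages would correlate
  cfg <- litter_sim_config(
    n_loci = 4000, allele_freq = c(0, 1), n_offspring = 1, mode = "ltss",
    dropout_rate = 0, miscall_rate = 0, missing_rate = 0, seed = 77
  )
  par <- simulate_parents(cfg)
  lit <- simulate_ltss_litter(cfg, const_parent(4000, 1L, 2L),
    list(const_parent(4000, 1L, 1L))
  )
  kid <- lit$genotypes[lit$genotypes$sample_id != "mother", ]
  got_2 <- kid$allele_2 == 2L # which maternal allele was transmitted
  r <- suppressWarnings(cor(par$allele_freq, as.numeric(got_2)))
  expect_lt(abs(r), 3 / sqrt(4000))
})
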