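#' Litter simulation configuration
#'
#' Parameterises a synthetic mother-plus-litter genotype matrix. Two
#' reproductive modes are modelled:
#'
#' * **`"ltss"`** (long-term sperm storage, i.e. ordinary sexual
#'   reproduction): each offspring receives one uniformly chosen maternal
#'   allele and one allele transmitted by its assigned sire, independently
#'   across loci.
#' * **`"fp_*"`** (facultative parthenogenesis by automixis):
#'   `fp_gametic_duplication` doubles a single meiotic product, so offspring
#'   are homozygous at every locus for one uniformly chosen maternal allele;
#'   `fp_terminal_fusion` and `fp_central_fusion` copy the mother at her
#'   homozygous loci, while at her heterozygous loci offspring stay
#'   heterozygous with probability `het_retention` and otherwise become
#'   homozygous for a uniformly chosen maternal allele. Terminal fusion
#'   retains little heterozygosity (crossover-proximal sites only); central
#'   fusion retains much more — the single scalar `het_retention` stands in
#'   for that map-dependent detail. Parthenogens in ZW taxa are male (ZZ; WW
#'   is inviable), so FP offspring are all-male by construction.
#'
#' Alleles are coded 1 (reference) and 2 (alternate); parental genotypes are
#' drawn under Hardy-Weinberg equilibrium from per-locus reference-allele
#' frequencies.
#'
#' @param n_loci Number of biallelic loci.
#' @param allele_freq Reference-allele frequency specification: a single
#'   value used at every locus, or a length-2 range `c(a, b)` from which
#'   per-locus frequencies are drawn uniformly. The default `c(0.05, 0.95)`
#'   mimics the frequency spread of RAD SNPs that survive a light MAF
#'   filter.
#' @param n_offspring Litter size (sampled offspring).
#' @param sex_ratio Probability an LTSS offspring is male.
#' @param mode Reproductive mode; see Details above.
#' @param n_sires Number of sires (LTSS only; must be unset for `fp_*`
#'   modes).
#' @param sire_assignment `"random"` or an integer vector of per-offspring
#'   sire indices.
#' @param het_retention Per-locus probability that a maternal heterozygous
#'   locus stays heterozygous under terminal/central fusion.
#' @param dropout_rate,miscall_rate,missing_rate Genotyping-error overlay
#'   rates; see [apply_genotyping_error()]. The defaults are placeholders of
#'   realistic magnitude for RAD data, not estimates from any particular
#'   dataset.
#' @param n_infertile_ova Count of infertile ova observed with the litter
#'   (metadata only; carries no genotypes).
#' @param seed Integer seed; the same seed and configuration reproduce the
#'   output exactly.
#' @return An object of class `litter_sim_config`.
#' @examples
#' cfg <- litter_sim_config(n_loci = 100, n_offspring = 5, seed = 1)
#' sim <- simulate_litter(cfg)
#' sim$meta
#' @export
litter_sim_config <- function(n_loci = 500,
                              allele_freq = c(0.05, 0.95),
                              n_offspring = 5,
                              sex_ratio = 0.5,
                              mode = c(
                                "ltss", "fp_terminal_fusion",
                                "fp_central_fusion", "fp_gametic_duplication"
                              ),
                              n_sires = NULL,
                              sire_assignment = "random",
                              het_retention = 0.3,
                              dropout_rate = 0.01,
                              miscall_rate = 0.005,
                              missing_rate = 0,
                              n_infertile_ova = 0,
                              seed = NULL) {
  mode <- match.arg(mode)
  chk_count <- function(x, nm, min = 0) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != round(x)) {
      abort(sprintf("%s must be an integer >= %d", nm, min))
    }
    as.integer(x)
  }
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      abort(sprintf("%s must be a probability in [0, 1]", nm))
    }
    as.numeric(x)
  }
  n_loci <- chk_count(n_loci, "n_loci")
  n_offspring <- chk_count(n_offspring, "n_offspring")
  if (!is.numeric(allele_freq) || !length(allele_freq) %in% c(1, 2) ||
    any(is.na(allele_freq)) || any(allele_freq < 0) || any(allele_freq > 1)) {
    abort("allele_freq must be one probability or a range c(a, b) in [0, 1]")
  }
  if (length(allele_freq) == 2 && allele_freq[1] > allele_freq[2]) {
    abort("allele_freq range must have a <= b")
  }
  if (mode == "ltss") {
    n_sires <- chk_count(n_sires %||% 1L, "n_sires", min = 1)
  } else if (!is.null(n_sires)) {
    abort("n_sires cannot be set for fp_* modes (parthenogens have no sire)")
  }
  if (!identical(sire_assignment, "random")) {
    sire_assignment <- as.integer(sire_assignment)
    if (length(sire_assignment) != n_offspring || anyNA(sire_assignment)) {
      abort("sire_assignment must be 'random' or one sire index per offspring")
    }
  }
  if (!is.null(seed)) seed <- chk_count(seed, "seed")
  structure(
    list(
      n_loci = n_loci, allele_freq = as.numeric(allele_freq),
      n_offspring = n_offspring, sex_ratio = chk_prob(sex_ratio, "sex_ratio"),
      mode = mode, n_sires = n_sires, sire_assignment = sire_assignment,
      het_retention = chk_prob(het_retention, "het_retention"),
      dropout_rate = chk_prob(dropout_rate, "dropout_rate"),
      miscall_rate = chk_prob(miscall_rate, "miscall_rate"),
      missing_rate = chk_prob(missing_rate, "missing_rate"),
      n_infertile_ova = chk_count(n_infertile_ova, "n_infertile_ova"),
      seed = seed
    ),
    class = "litter_sim_config"
  )
}

## evaluate expr under an optional fixed seed, offset so that the parent,
## litter and error stages draw from decorrelated streams
with_stage_seed <- function(seed, offset, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer((seed + offset) %% 2147483629L), expr)
  }
}

#' Draw parental genotypes under Hardy-Weinberg equilibrium
#'
#' The mother and (for LTSS configurations) each sire get two independent
#' alleles per locus, reference with the per-locus probability given by the
#' configuration's `allele_freq`.
#'
#' @param cfg A [litter_sim_config()].
#' @param seed Seed for this stage; defaults to the configuration's seed.
#' @return A list with `mother` (tibble `locus_id`, `allele_1`, `allele_2`),
#'   `sires` (list of such tibbles, empty for `fp_*` modes), `allele_freq`
#'   (per-locus reference frequency) and `loci`.
#' @export
simulate_parents <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "litter_sim_config"))
  with_stage_seed(seed, 0L, {
    loci <- if (cfg$n_loci > 0) sprintf("locus_%d", seq_len(cfg$n_loci)) else character()
    p <- if (length(cfg$allele_freq) == 1) {
      rep(cfg$allele_freq, cfg$n_loci)
    } else {
      runif(cfg$n_loci, cfg$allele_freq[1], cfg$allele_freq[2])
    }
    draw_ind <- function() {
      a <- ifelse(runif(cfg$n_loci) < p, 1L, 2L)
      b <- ifelse(runif(cfg$n_loci) < p, 1L, 2L)
      tibble(
        locus_id = loci, allele_1 = pmin(a, b), allele_2 = pmax(a, b)
      )
    }
    mother <- draw_ind()
    n_sires <- if (cfg$mode == "ltss") cfg$n_sires else 0L
    sires <- replicate(n_sires, draw_ind(), simplify = FALSE)
    list(mother = mother, sires = sires, allele_freq = p, loci = loci)
  })
}

offspring_ids <- function(n) sprintf("off_%02d", seq_len(n))

litter_meta <- function(off_ids, sex, n_infertile_ova) {
  meta <- tibble(
    sample_id = c("mother", off_ids),
    role = c("mother", rep("offspring", length(off_ids))),
    sex = c("female", sex)
  )
  attr(meta, "n_infertile_ova") <- n_infertile_ova
  meta
}

#' Simulate a litter by Mendelian inheritance from stored sperm
#'
#' Each offspring receives, at every locus independently, one uniformly
#' chosen maternal allele and one allele transmitted by its assigned sire.
#' The genotyping-error overlay is *not* applied here; see
#' [apply_genotyping_error()] or the [simulate_litter()] wrapper.
#'
#' @inheritParams simulate_parents
#' @param mother Mother genotype tibble (`locus_id`, `allele_1`, `allele_2`),
#'   e.g. from [simulate_parents()].
#' @param sires List of sire genotype tibbles in the same format.
#' @return A list with `genotypes` (a [geno_tbl][as_geno_tbl] holding the
#'   mother and all offspring), `meta` (sample metadata) and `sire_of`
#'   (integer sire index per offspring — the simulation truth).
#' @export
simulate_ltss_litter <- function(cfg, mother, sires, seed = cfg$seed) {
  stopifnot(inherits(cfg, "litter_sim_config"))
  if (cfg$mode != "ltss") abort("cfg$mode must be 'ltss'")
  n_off <- cfg$n_offspring
  n_loci <- nrow(mother)
  with_stage_seed(seed, 1L, {
    sire_of <- if (identical(cfg$sire_assignment, "random")) {
      sample.int(length(sires), n_off, replace = TRUE)
    } else {
      cfg$sire_assignment
    }
    if (any(sire_of < 1 | sire_of > length(sires))) {
      abort("sire index out of range")
    }
    off <- purrr::map(seq_len(n_off), function(o) {
      s <- sires[[sire_of[o]]]
      mat <- ifelse(runif(n_loci) < 0.5, mother$allele_1, mother$allele_2)
      pat <- ifelse(runif(n_loci) < 0.5, s$allele_1, s$allele_2)
      tibble(
        sample_id = offspring_ids(n_off)[o], locus_id = mother$locus_id,
        allele_1 = pmin(mat, pat), allele_2 = pmax(mat, pat)
      )
    })
    sex <- ifelse(runif(n_off) < cfg$sex_ratio, "male", "female")
    g <- as_geno_tbl(dplyr::bind_rows(
      tibble(
        sample_id = "mother", locus_id = mother$locus_id,
        allele_1 = mother$allele_1, allele_2 = mother$allele_2
      ),
      off
    ))
    list(
      genotypes = g,
      meta = litter_meta(offspring_ids(n_off), sex, cfg$n_infertile_ova),
      sire_of = sire_of
    )
  })
}

#' Simulate a parthenogenetic litter by automixis
#'
#' Implements the automixis variants described in [litter_sim_config()].
#' Offspring never carry an allele absent from the mother, and all offspring
#' are male (ZZ under ZW sex determination). Error overlay not applied.
#'
#' @inheritParams simulate_ltss_litter
#' @return A list with `genotypes` and `meta` as in
#'   [simulate_ltss_litter()].
#' @export
simulate_fp_litter <- function(cfg, mother, seed = cfg$seed) {
  stopifnot(inherits(cfg, "litter_sim_config"))
  if (!startsWith(cfg$mode, "fp_")) abort("cfg$mode must be an fp_* mode")
  n_off <- cfg$n_offspring
  n_loci <- nrow(mother)
  with_stage_seed(seed, 1L, {
    mom_het <- mother$allele_1 != mother$allele_2
    off <- purrr::map(seq_len(n_off), function(o) {
      if (cfg$mode == "fp_gametic_duplication") {
        a <- ifelse(runif(n_loci) < 0.5, mother$allele_1, mother$allele_2)
        a1 <- a
        a2 <- a
      } else {
        keep_het <- mom_het & runif(n_loci) < cfg$het_retention
        pick <- ifelse(runif(n_loci) < 0.5, mother$allele_1, mother$allele_2)
        a1 <- ifelse(keep_het, mother$allele_1, pick)
        a2 <- ifelse(keep_het, mother$allele_2, pick)
      }
      tibble(
        sample_id = offspring_ids(n_off)[o], locus_id = mother$locus_id,
        allele_1 = pmin(a1, a2), allele_2 = pmax(a1, a2)
      )
    })
    g <- as_geno_tbl(dplyr::bind_rows(
      tibble(
        sample_id = "mother", locus_id = mother$locus_id,
        allele_1 = mother$allele_1, allele_2 = mother$allele_2
      ),
      off
    ))
    list(
      genotypes = g,
      meta = litter_meta(
        offspring_ids(n_off), rep("male", n_off), cfg$n_infertile_ova
      )
    )
  })
}

#' Overlay genotyping error on a genotype table
#'
#' Applies, per cell and in this fixed order: with probability
#' `missing_rate` the cell becomes missing; otherwise, if the cell is
#' heterozygous, with probability `dropout_rate` it is replaced by one of
#' its two homozygotes uniformly (allelic dropout); otherwise with
#' probability `miscall_rate` it is replaced by a genotype drawn uniformly
#' from the three genotypes of the biallelic allele universe (which may
#' reproduce the original call). The order mirrors the physical hierarchy
#' no call > partial signal > wrong call and keeps closed-form error
#' expectations computable.
#'
#' Random draws are keyed to cells in sorted `(sample_id, locus_id)` order,
#' so the overlay commutes exactly with row reordering under a fixed seed.
#'
#' @param g A genotype table.
#' @param dropout_rate,miscall_rate,missing_rate Per-cell probabilities.
#' @param alleles Length-2 integer allele universe for miscalls. Defaults to
#'   the codes observed in `g`, padded with codes 1 and 2 when fewer than
#'   two are observed (so miscalls on monomorphic input can still introduce
#'   the alternate allele of the underlying biallelic SNP).
#' @param seed Optional seed for this stage.
#' @return A genotype table of the same shape and row order.
#' @export
apply_genotyping_error <- function(g, dropout_rate = 0, miscall_rate = 0,
                                   missing_rate = 0, alleles = NULL,
                                   seed = NULL) {
  g <- as_geno_tbl(g)
  for (r in c(dropout_rate, miscall_rate, missing_rate)) {
    if (!is.numeric(r) || length(r) != 1 || is.na(r) || r < 0 || r > 1) {
      abort("error rates must be probabilities in [0, 1]")
    }
  }
  if (is.null(alleles)) {
    obs <- sort(unique(c(g$allele_1, g$allele_2)))
    obs <- obs[!is.na(obs)]
    alleles <- utils::head(unique(c(obs, 1L, 2L)), 2)
  }
  alleles <- sort(as.integer(alleles))
  if (length(alleles) != 2) abort("alleles must give two distinct codes")

  ord <- order(g$sample_id, g$locus_id)
  a1 <- g$allele_1[ord]
  a2 <- g$allele_2[ord]
  n <- length(a1)
  with_stage_seed(seed, 2L, {
    u_miss <- runif(n)
    u_drop <- runif(n)
    pick_drop <- runif(n) < 0.5
    u_mis <- runif(n)
    pick_mis <- sample.int(3L, n, replace = TRUE)

    miss <- u_miss < missing_rate
    het <- !is.na(a1) & a1 != a2
    drop <- !miss & het & u_drop < dropout_rate
    kept <- ifelse(pick_drop, a1, a2)
    a1[drop] <- kept[drop]
    a2[drop] <- kept[drop]
    mis <- !miss & !drop & !is.na(a1) & u_mis < miscall_rate
    g1 <- c(alleles[1], alleles[1], alleles[2])
    g2 <- c(alleles[1], alleles[2], alleles[2])
    a1[mis] <- g1[pick_mis[mis]]
    a2[mis] <- g2[pick_mis[mis]]
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
  })
  out <- g
  out$allele_1[ord] <- a1
  out$allele_2[ord] <- a2
  as_geno_tbl(out)
}

#' Simulate a complete litter with error overlay
#'
#' Convenience wrapper running [simulate_parents()], the mode-appropriate
#' litter generator and [apply_genotyping_error()] under the
#' configuration's seed and error rates.
#'
#' @inheritParams simulate_parents
#' @return A list with `genotypes` (error-overlaid), `genotypes_true`
#'   (pre-error), `meta`, `truth` (list: `mode`, `sire_of`, `mother`,
#'   `sires`, `allele_freq`).
#' @export
simulate_litter <- function(cfg) {
  stopifnot(inherits(cfg, "litter_sim_config"))
  parents <- simulate_parents(cfg)
  lit <- if (cfg$mode == "ltss") {
    simulate_ltss_litter(cfg, parents$mother, parents$sires)
  } else {
    simulate_fp_litter(cfg, parents$mother)
  }
  noisy <- apply_genotyping_error(
    lit$genotypes,
    dropout_rate = cfg$dropout_rate, miscall_rate = cfg$miscall_rate,
    missing_rate = cfg$missing_rate, alleles = c(1L, 2L), seed = cfg$seed
  )
  list(
    genotypes = noisy,
    genotypes_true = lit$genotypes,
    meta = lit$meta,
    truth = list(
      mode = cfg$mode, sire_of = lit$sire_of %||% NULL,
      mother = parents$mother, sires = parents$sires,
      allele_freq = parents$allele_freq
    )
  )
}
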