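#' Locus filters
#'
#' Standard pre-scan locus filters for RAD-seq genotype tables. Both filters
#' keep sample order untouched and preserve the relative order of the loci
#' they retain, and both are idempotent.
#'
#' `filter_complete_loci()` keeps loci genotyped (non-missing) in at least
#' `r * n_samples` samples; `r = 1` keeps only loci present in every
#' individual, the usual setting before a paternal-allele scan so that every
#' retained locus is evaluable in every offspring.
#'
#' `filter_maf()` computes each locus's minor allele frequency by counting
#' alleles over non-missing genotypes across all samples and keeps loci with
#' MAF at least `threshold` (`mode = "ge"`) or, for the exact-frequency
#' variant, equal to `threshold` within 1e-9 (`mode = "eq"`). Loci with more
#' than two observed alleles are dropped with a warning (`drop_multiallelic =
#' FALSE` raises an error instead): downstream scan and sibship math assumes
#' biallelic SNPs.
#'
#' @param g A genotype table ([as_geno_tbl]).
#' @param r Required fraction of genotyped samples, in \[0, 1\].
#' @return A filtered genotype table.
#' @examples
#' g <- as_geno_tbl(data.frame(
#'   sample_id = rep(c("a", "b"), each = 2),
#'   locus_id = rep(c("L1", "L2"), 2),
#'   allele_1 = c(1L, 1L, NA, 1L), allele_2 = c(2L, 1L, NA, 2L)
#' ))
#' geno_loci(filter_complete_loci(g, r = 1))
#' geno_loci(filter_maf(g, threshold = 0.5))
#' @export
filter_complete_loci <- function(g, r = 1) {
  g <- as_geno_tbl(g)
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || r < 0 || r > 1) {
    abort("r must be a single number in [0, 1]")
  }
  n_samples <- length(geno_samples(g))
  counts <- g |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(n_called = sum(!is.na(.data$allele_1)), .groups = "drop")
  keep <- counts$locus_id[counts$n_called >= r * n_samples - 1e-9]
  dplyr::filter(g, .data$locus_id %in% keep)
}

#' @rdname filter_complete_loci
#' @param threshold Minor-allele-frequency threshold, in \[0, 0.5\].
#' @param mode `"ge"` keeps MAF >= threshold; `"eq"` keeps MAF equal to
#'   threshold within 1e-9.
#' @param drop_multiallelic Drop loci with > 2 observed alleles (with a
#'   warning) rather than erroring.
#' @export
filter_maf <- function(g, threshold = 0.05, mode = c("ge", "eq"),
                       drop_multiallelic = TRUE) {
  g <- as_geno_tbl(g)
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
    threshold < 0 || threshold > 0.5) {
    abort("threshold must be a single number in [0, 0.5]")
  }
  fr <- locus_allele_freqs(g, warn_multiallelic = FALSE)
  multi <- fr$locus_id[fr$n_alleles > 2]
  if (length(multi) > 0) {
    if (!drop_multiallelic) {
      abort(paste0(
        "loci with more than two alleles: ", paste(multi, collapse = ", ")
      ))
    }
    warn(sprintf("dropping %d locus/loci with more than two alleles", length(multi)))
  }
  fr <- fr[fr$n_alleles <= 2, , drop = FALSE]
  keep <- switch(mode,
    ge = fr$locus_id[fr$maf >= threshold - 1e-9],
    eq = fr$locus_id[abs(fr$maf - threshold) <= 1e-9]
  )
  dplyr::filter(g, .data$locus_id %in% keep)
}

#' Per-locus allele frequencies
#'
#' Tallies allele codes over non-missing genotypes, across all samples
#' (including the mother; with litter-sized samples there is no unbiased
#' alternative and this matches what a naive analysis would do). For each
#' locus the two allele codes are reported in ascending code order with the
#' frequency of the first; monomorphic loci report `allele_b = NA` and
#' `freq_a = 1`.
#'
#' @inheritParams filter_complete_loci
#' @param warn_multiallelic Warn when a locus shows more than two alleles.
#' @return A tibble with columns `locus_id`, `allele_a`, `allele_b`,
#'   `freq_a`, `maf`, `n_obs` (allele observations), `n_alleles`.
#' @export
locus_allele_freqs <- function(g, warn_multiallelic = TRUE) {
  g <- as_geno_tbl(g)
  loci <- geno_loci(g)
  long <- tibble(
    locus_id = rep(g$locus_id, 2L),
    allele = c(g$allele_1, g$allele_2)
  )
  long <- long[!is.na(long$allele), , drop = FALSE]
  tallied <- long |>
    dplyr::count(.data$locus_id, .data$allele) |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::arrange(.data$allele, .by_group = TRUE) |>
    dplyr::summarise(
      allele_a = .data$allele[1],
      allele_b = if (dplyr::n() >= 2) .data$allele[2] else NA_integer_,
      freq_a = .data$n[1] / sum(.data$n),
      maf = if (dplyr::n() == 1) 0 else min(.data$n[1:2]) / sum(.data$n[1:2]),
      n_obs = sum(.data$n),
      n_alleles = dplyr::n(),
      .groups = "drop"
    )
  out <- tallied[match(loci, tallied$locus_id), , drop = FALSE]
  out$locus_id <- loci
  out$n_obs[is.na(out$n_obs)] <- 0L
  out$n_alleles[is.na(out$n_alleles)] <- 0L
  out$maf[is.na(out$maf)] <- 0 # loci with no observed alleles
  out$freq_a[is.na(out$freq_a) & out$n_alleles == 0] <- NA_real_
  if (warn_multiallelic && any(out$n_alleles > 2)) {
    warn(sprintf(
      "%d locus/loci show more than two alleles", sum(out$n_alleles > 2)
    ))
  }
  out
}
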