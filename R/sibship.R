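#' Pairwise full-sib versus half-sib log-likelihood ratio
#'
#' With the mother known, two offspring are full sibs exactly when they
#' share a sire. For each locus the likelihood of the observed offspring
#' genotype pair is computed under two hypotheses:
#'
#' * **full-sib**: one father, genotype drawn from Hardy-Weinberg
#'   proportions at the locus's allele frequency, transmitting
#'   independently to both offspring;
#' * **half-sib**: two independent fathers, each drawn from the same
#'   Hardy-Weinberg prior.
#'
#' Offspring genotypes are observed through a symmetric error channel that
#' replaces the true genotype with a uniform draw from the three biallelic
#' genotypes at rate `error_rate` (the single per-SNP genotyping-error
#' scalar used by standard sibship software). The mother's observed
#' genotype is taken as true. Loci are treated as independent and the
#' log-likelihood ratio is the sum of per-locus log ratios; positive values
#' favour full sibs.
#'
#' Loci are skipped when the mother or either offspring is missing, the
#' locus is not informatively biallelic (monomorphic or > 2 alleles), or a
#' genotype carries an allele outside the locus's frequency table. If no
#' locus is usable the function errors rather than returning a silent zero.
#'
#' @param g A genotype table.
#' @param mother_id Mother sample id.
#' @param off_i,off_j Offspring sample ids.
#' @param allele_freqs Per-locus allele frequencies as from
#'   [locus_allele_freqs()]; computed from all samples of `g` (mother
#'   included) when `NULL`. Estimating frequencies from the very samples
#'   being tested slightly biases the LLR toward relatedness; with
#'   litter-only data there is no outgroup to estimate from, and the
#'   clustering step only uses LLR contrasts.
#' @param error_rate Per-SNP genotyping error rate in \[0, 1).
#' @return A single finite log-likelihood ratio (natural log), with
#'   attribute `n_loci_used`.
#' @examples
#' cfg <- litter_sim_config(n_loci = 300, n_offspring = 4,
#'   allele_freq = c(0.3, 0.7), dropout_rate = 0, miscall_rate = 0, seed = 2)
#' sim <- simulate_litter(cfg)
#' pairwise_sib_llr(sim$genotypes, "mother", "off_01", "off_02")
#' @export
pairwise_sib_llr <- function(g, mother_id, off_i, off_j,
                             allele_freqs = NULL, error_rate = 0.05) {
  enc <- sib_encode(g, mother_id, c(off_i, off_j), allele_freqs, error_rate)
  use <- !is.na(enc$off[, 1]) & !is.na(enc$off[, 2])
  if (!any(use)) {
    abort("no usable locus for sibship likelihood (all missing or uninformative)")
  }
  llr <- sib_llr_from_encoding(
    enc$f2[use], enc$m[use], enc$off[use, 1], enc$off[use, 2], error_rate
  )
  structure(llr$llr, n_loci_used = llr$n_used)
}

## Encode genotypes as counts of the locus's higher-coded allele (allele_b).
## Returns per-locus second-allele frequency f2, mother count m and an
## offspring count matrix; loci failing the usability rules are dropped.
sib_encode <- function(g, mother_id, offspring, allele_freqs, error_rate) {
  g <- as_geno_tbl(g)
  if (!is.numeric(error_rate) || length(error_rate) != 1 ||
    is.na(error_rate) || error_rate < 0 || error_rate >= 1) {
    abort("error_rate must lie in [0, 1)")
  }
  samples <- geno_samples(g)
  for (id in c(mother_id, offspring)) {
    if (!id %in% samples) abort(sprintf("sample '%s' not in genotype table", id))
  }
  fr <- allele_freqs %||% locus_allele_freqs(g, warn_multiallelic = FALSE)
  fr <- fr[fr$n_alleles == 2 & fr$freq_a > 0 & fr$freq_a < 1, , drop = FALSE]
  m <- as_geno_matrices(g)
  loci <- intersect(m$loci, fr$locus_id)
  fr <- fr[match(loci, fr$locus_id), , drop = FALSE]

  count_b <- function(id) {
    a1 <- m$a1[id, loci]
    a2 <- m$a2[id, loci]
    ok <- !is.na(a1) &
      (a1 == fr$allele_a | a1 == fr$allele_b) &
      (a2 == fr$allele_a | a2 == fr$allele_b)
    cnt <- (a1 == fr$allele_b) + (a2 == fr$allele_b)
    ifelse(ok, as.numeric(cnt), NA_real_)
  }
  mom <- count_b(mother_id)
  off <- vapply(offspring, count_b, numeric(length(loci)))
  if (length(loci) <= 1) {
    off <- matrix(off, nrow = length(loci), ncol = length(offspring))
  }
  usable <- !is.na(mom)
  if (!any(usable)) {
    abort("no usable locus for sibship likelihood (all missing or uninformative)")
  }
  list(
    f2 = 1 - fr$freq_a[usable],
    m = mom[usable],
    off = off[usable, , drop = FALSE],
    loci = loci[usable]
  )
}

## Vectorised per-locus likelihoods. m, oi, oj are counts (0/1/2) of the
## second allele; f2 its frequency. Father genotype gf is marginalised over
## HWE priors; transmission closed forms follow from independent maternal
## (m/2) and paternal (gf/2) second-allele transmission probabilities.
sib_llr_from_encoding <- function(f2, m, oi, oj, error_rate) {
  eps <- error_rate
  mm <- m / 2
  prior <- cbind((1 - f2)^2, 2 * f2 * (1 - f2), f2^2)
  a_i <- matrix(0, length(f2), 3)
  a_j <- a_i
  for (gf in 0:2) {
    ff <- gf / 2
    pt <- cbind(
      (1 - mm) * (1 - ff),
      mm + ff - 2 * mm * ff,
      mm * ff
    )
    pick <- function(o) pt[cbind(seq_along(o), o + 1L)]
    a_i[, gf + 1] <- (1 - eps) * pick(oi) + eps / 3
    a_j[, gf + 1] <- (1 - eps) * pick(oj) + eps / 3
  }
  l_fs <- rowSums(prior * a_i * a_j)
  l_hs <- rowSums(prior * a_i) * rowSums(prior * a_j)
  list(llr = sum(log(l_fs) - log(l_hs)), n_used = length(f2))
}

#' Partition a litter into paternal sibships
#'
#' Computes [pairwise_sib_llr()] for every offspring pair, links pairs whose
#' LLR meets `llr_threshold` (ties at the threshold are linked) and takes
#' connected components as full-sibships. With the mother shared, the number
#' of components is the minimum number of sires consistent with the
#' pairwise evidence. This is a deliberate simplification of full pedigree
#' reconstruction: no MCMC, no sibship-size prior, no parental-genotype
#' inference — just the minimum-sire count and the grouping.
#'
#' @inheritParams pairwise_sib_llr
#' @param offspring_ids Offspring to cluster (>= 2); default all non-mother
#'   samples.
#' @param llr_threshold LLR at or above which a pair is linked (default 0,
#'   i.e. full-sib at least as likely as half-sib).
#' @return An object of class `sibship_partition`: `clusters` (list of
#'   offspring-id sets), `n_sires_min`, `pairwise` tibble (`id_i`, `id_j`,
#'   `llr`, `n_loci_used`, `linked`), `error_rate`, `llr_threshold`.
#'   [tidy()] returns the pairwise tibble, [glance()] a one-row summary.
#' @export
partition_sibships <- function(g, mother_id, offspring_ids = NULL,
                               allele_freqs = NULL, error_rate = 0.05,
                               llr_threshold = 0) {
  g <- as_geno_tbl(g)
  offspring_ids <- offspring_ids %||% setdiff(geno_samples(g), mother_id)
  if (length(offspring_ids) < 2) {
    abort("partition_sibships needs at least two offspring")
  }
  allele_freqs <- allele_freqs %||% locus_allele_freqs(g, warn_multiallelic = FALSE)
  enc <- sib_encode(g, mother_id, offspring_ids, allele_freqs, error_rate)

  pairs <- utils::combn(seq_along(offspring_ids), 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    use <- !is.na(enc$off[, i]) & !is.na(enc$off[, j])
    if (!any(use)) {
      abort(sprintf(
        "no usable locus for pair %s / %s",
        offspring_ids[i], offspring_ids[j]
      ))
    }
    ll <- sib_llr_from_encoding(
      enc$f2[use], enc$m[use], enc$off[use, i], enc$off[use, j], error_rate
    )
    tibble(
      id_i = offspring_ids[i], id_j = offspring_ids[j],
      llr = ll$llr, n_loci_used = ll$n_used
    )
  })
  pairwise$linked <- pairwise$llr >= llr_threshold

  gr <- igraph::graph_from_data_frame(
    pairwise[pairwise$linked, c("id_i", "id_j")],
    directed = FALSE,
    vertices = data.frame(name = offspring_ids)
  )
  comp <- igraph::components(gr)
  clusters <- split(offspring_ids, comp$membership[offspring_ids])
  clusters <- unname(clusters[order(vapply(clusters, function(cl) {
    match(cl[1], offspring_ids)
  }, integer(1)))])

  structure(
    list(
      clusters = clusters,
      n_sires_min = length(clusters),
      pairwise = pairwise,
      mother_id = mother_id,
      offspring_ids = offspring_ids,
      error_rate = error_rate,
      llr_threshold = llr_threshold
    ),
    class = "sibship_partition"
  )
}

#' @export
print.sibship_partition <- function(x, ...) {
  cat("Sibship partition (pairwise full-sib vs half-sib LLR)\n")
  cat(sprintf(
    "  offspring: %d | error rate: %.3g | link threshold: %.3g\n",
    length(x$offspring_ids), x$error_rate, x$llr_threshold
  ))
  cat(sprintf("  minimum number of sires: %d\n", x$n_sires_min))
  for (i in seq_along(x$clusters)) {
    cat(sprintf(
      "  sibship %d: %s\n", i, paste(x$clusters[[i]], collapse = ", ")
    ))
  }
  invisible(x)
}

#' @method tidy sibship_partition
#' @export
tidy.sibship_partition <- function(x, ...) x$pairwise

#' @method glance sibship_partition
#' @export
glance.sibship_partition <- function(x, ...) {
  tibble(
    n_offspring = length(x$offspring_ids),
    n_sires_min = x$n_sires_min,
    min_llr = min(x$pairwise$llr),
    max_llr = max(x$pairwise$llr),
    error_rate = x$error_rate,
    llr_threshold = x$llr_threshold
  )
}

#' @method autoplot sibship_partition
#' @export
autoplot.sibship_partition <- function(object, ...) {
  d <- object$pairwise
  d2 <- dplyr::bind_rows(
    d,
    dplyr::rename(d, id_i = "id_j", id_j = "id_i")
  )
  ggplot2::ggplot(d2, ggplot2::aes(.data$id_i, .data$id_j, fill = .data$llr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = object$llr_threshold) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "LLR",
      title = sprintf(
        "Pairwise full-sib LLR (min sires: %d)", object$n_sires_min
      )
    )
}
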