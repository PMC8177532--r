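#' Loci at which the mother is homozygous
#'
#' At a locus where the mother carries two copies of one allele, any other
#' allele observed in her offspring must have come from a father (barring
#' genotyping error) — these loci are the informative substrate of the
#' paternal-allele scan. Loci where the mother's genotype is missing are
#' excluded.
#'
#' @param g A genotype table ([as_geno_tbl]).
#' @param mother_id Sample id of the mother.
#' @return Character vector of locus ids, in the table's locus order.
#' @export
find_maternal_homozygous_loci <- function(g, mother_id) {
  g <- as_geno_tbl(g)
  if (!mother_id %in% geno_samples(g)) {
    abort(sprintf("mother_id '%s' not found in genotype table", mother_id))
  }
  mom <- dplyr::filter(g, .data$sample_id == mother_id)
  mom$locus_id[!is.na(mom$allele_1) & mom$allele_1 == mom$allele_2]
}

#' Scan offspring for putative paternal alleles
#'
#' The core computation: at every locus where the mother is homozygous, each
#' offspring is flagged when its (non-missing) genotype contains at least
#' one allele different from the maternal allele. Two litter-level counts
#' summarise the flags:
#'
#' * `conservative_count` — loci at which *all* offspring are flagged. Since
#'   genotyping error rarely strikes every offspring at the same locus,
#'   these loci are strong evidence of a paternal contribution shared by the
#'   whole litter. Under the default `missing_policy = "strict"` a locus
#'   with any missing offspring call is excluded from the conservative set;
#'   `"evaluated_only"` requires only that every *called* offspring is
#'   flagged (at least one must be called).
#' * `liberal_count` — loci at which *any* offspring is flagged.
#'
#' @inheritParams find_maternal_homozygous_loci
#' @param offspring_ids Offspring to evaluate; defaults to every sample
#'   other than the mother. A ZW-system replication of a males-only design
#'   passes the male offspring ids here.
#' @param missing_policy `"strict"` or `"evaluated_only"`; see above.
#' @return An object of class `paternal_scan` with fields `loci`
#'   (maternal-homozygous locus ids), `maternal_allele`, `flags`
#'   (offspring x locus logical matrix, `NA` where the offspring call is
#'   missing), `per_offspring` (tibble: `sample_id`, `n_evaluated`,
#'   `n_flagged`, `paternal_fraction`), `conservative_loci`,
#'   `conservative_count`, `liberal_count`. [tidy()] returns the flags in
#'   long form, [glance()] the litter-level counts.
#' @examples
#' cfg <- litter_sim_config(n_loci = 200, n_offspring = 5, mode = "ltss",
#'   dropout_rate = 0, miscall_rate = 0, seed = 7)
#' sim <- simulate_litter(cfg)
#' scan <- scan_paternal_alleles(sim$genotypes, "mother")
#' glance(scan)
#' @export
scan_paternal_alleles <- function(g, mother_id, offspring_ids = NULL,
                                  missing_policy = c("strict", "evaluated_only")) {
  g <- as_geno_tbl(g)
  missing_policy <- match.arg(missing_policy)
  if (nrow(g) == 0) {
    warn("empty genotype table: scan has no loci to evaluate")
    offspring_ids <- offspring_ids %||% character()
    return(new_paternal_scan(
      mother_id, offspring_ids, missing_policy,
      loci = character(), maternal_allele = integer(),
      flags = matrix(NA, length(offspring_ids), 0,
        dimnames = list(offspring_ids, NULL)
      ),
      n_loci_total = 0L
    ))
  }
  samples <- geno_samples(g)
  if (!mother_id %in% samples) {
    abort(sprintf("mother_id '%s' not found in genotype table", mother_id))
  }
  offspring_ids <- offspring_ids %||% setdiff(samples, mother_id)
  if (length(offspring_ids) == 0) abort("offspring_ids must be non-empty")
  if (mother_id %in% offspring_ids) {
    abort("mother_id cannot appear among offspring_ids")
  }
  if (!all(offspring_ids %in% samples)) {
    abort(paste0(
      "offspring not in genotype table: ",
      paste(setdiff(offspring_ids, samples), collapse = ", ")
    ))
  }

  m <- as_geno_matrices(g)
  hom <- find_maternal_homozygous_loci(g, mother_id)
  if (length(hom) == 0) {
    warn("mother is homozygous at no locus: scan result is empty")
  }
  mat_allele <- m$a1[mother_id, hom]
  o1 <- m$a1[offspring_ids, hom, drop = FALSE]
  o2 <- m$a2[offspring_ids, hom, drop = FALSE]
  ma <- matrix(mat_allele,
    nrow = length(offspring_ids), ncol = length(hom), byrow = TRUE
  )
  flags <- (o1 != ma) | (o2 != ma) # NA where offspring call missing
  dimnames(flags) <- list(offspring_ids, hom)

  new_paternal_scan(
    mother_id, offspring_ids, missing_policy,
    loci = hom, maternal_allele = setNames(as.integer(mat_allele), hom),
    flags = flags, n_loci_total = length(m$loci)
  )
}

new_paternal_scan <- function(mother_id, offspring_ids, missing_policy,
                              loci, maternal_allele, flags, n_loci_total) {
  n_eval <- rowSums(!is.na(flags))
  n_flag <- rowSums(flags, na.rm = TRUE)
  frac <- ifelse(n_eval > 0, n_flag / n_eval, NA_real_)
  if (length(n_eval) > 0 && any(n_eval == 0)) {
    warn(paste0(
      "offspring with no evaluable locus (paternal_fraction is NA): ",
      paste(names(which(n_eval == 0)) %||% offspring_ids[n_eval == 0],
        collapse = ", "
      )
    ))
  }
  per_offspring <- tibble(
    sample_id = offspring_ids,
    n_evaluated = as.integer(n_eval),
    n_flagged = as.integer(n_flag),
    paternal_fraction = as.numeric(frac)
  )
  n_called <- colSums(!is.na(flags))
  n_flagged_col <- colSums(flags, na.rm = TRUE)
  n_off <- length(offspring_ids)
  conservative <- if (missing_policy == "strict") {
    n_called == n_off & n_flagged_col == n_off
  } else {
    n_called > 0 & n_flagged_col == n_called
  }
  liberal <- n_flagged_col > 0
  structure(
    list(
      mother_id = mother_id,
      offspring_ids = offspring_ids,
      missing_policy = missing_policy,
      loci = loci,
      maternal_allele = maternal_allele,
      flags = flags,
      per_offspring = per_offspring,
      conservative_loci = loci[conservative],
      conservative_count = sum(conservative),
      liberal_count = sum(liberal),
      n_loci_total = n_loci_total
    ),
    class = "paternal_scan"
  )
}

#' @export
print.paternal_scan <- function(x, ...) {
  n_hom <- length(x$loci)
  cat("Paternal-allele scan\n")
  cat(sprintf(
    "  mother: %s | offspring evaluated: %d | missing policy: %s\n",
    x$mother_id, length(x$offspring_ids), x$missing_policy
  ))
  cat(sprintf(
    "  maternal-homozygous loci: %d of %d\n", n_hom, x$n_loci_total
  ))
  cat(sprintf(
    "  loci with paternal alleles in ALL offspring (conservative): %d (%.1f%%)\n",
    x$conservative_count,
    if (n_hom > 0) 100 * x$conservative_count / n_hom else 0
  ))
  cat(sprintf(
    "  loci with paternal alleles in ANY offspring (liberal):      %d\n",
    x$liberal_count
  ))
  print(x$per_offspring)
  invisible(x)
}

#' @method tidy paternal_scan
#' @export
tidy.paternal_scan <- function(x, ...) {
  if (length(x$loci) == 0 || length(x$offspring_ids) == 0) {
    return(tibble(
      sample_id = character(), locus_id = character(), flagged = logical()
    ))
  }
  tibble(
    sample_id = rep(rownames(x$flags), times = ncol(x$flags)),
    locus_id = rep(colnames(x$flags), each = nrow(x$flags)),
    flagged = as.vector(x$flags)
  )
}

#' @method glance paternal_scan
#' @export
glance.paternal_scan <- function(x, ...) {
  n_hom <- length(x$loci)
  tibble(
    n_offspring = length(x$offspring_ids),
    n_loci_total = x$n_loci_total,
    n_maternal_homozygous = n_hom,
    conservative_count = x$conservative_count,
    conservative_fraction = if (n_hom > 0) x$conservative_count / n_hom else NA_real_,
    liberal_count = x$liberal_count,
    missing_policy = x$missing_policy
  )
}

#' @method autoplot paternal_scan
#' @export
autoplot.paternal_scan <- function(object, ...) {
  d <- object$per_offspring
  frac_cons <- if (length(object$loci) > 0) {
    object$conservative_count / length(object$loci)
  } else {
    NA_real_
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$sample_id, .data$paternal_fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(
      yintercept = frac_cons, linetype = "dashed", colour = "firebrick"
    ) +
    ggplot2::labs(
      x = NULL, y = "fraction of maternal-homozygous loci flagged",
      title = "Putative paternal alleles per offspring",
      subtitle = sprintf(
        "dashed: conservative (all-offspring) fraction = %.3g", frac_cons
      )
    )
}

#' Per-sample heterozygosity
#'
#' Fraction of non-missing genotypes that are heterozygous, per sample.
#' Elevated homozygosity relative to the mother is the classic automixis
#' signature (terminal fusion and gametic duplication strip heterozygosity),
#' so this feeds the reproductive-mode classifier. A sample with no
#' non-missing calls gets `NA` with a warning rather than a silent zero.
#'
#' @inheritParams find_maternal_homozygous_loci
#' @param sample_ids Samples to evaluate; default all.
#' @return Tibble with `sample_id`, `n_called`, `n_het`, `heterozygosity`.
#' @export
offspring_heterozygosity <- function(g, sample_ids = NULL) {
  g <- as_geno_tbl(g)
  sample_ids <- sample_ids %||% geno_samples(g)
  if (!all(sample_ids %in% geno_samples(g))) {
    abort("sample_ids not all present in genotype table")
  }
  out <- g |>
    dplyr::filter(.data$sample_id %in% sample_ids) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_called = sum(!is.na(.data$allele_1)),
      n_het = sum(.data$allele_1 != .data$allele_2, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      heterozygosity = ifelse(.data$n_called > 0,
        .data$n_het / .data$n_called, NA_real_
      )
    )
  out <- out[match(sample_ids, out$sample_id), , drop = FALSE]
  if (anyNA(out$heterozygosity)) {
    warn("sample(s) with zero non-missing calls: heterozygosity is NA")
  }
  out
}
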