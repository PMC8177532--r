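#' Reproductive-mode classification thresholds
#'
#' Decision thresholds on the per-offspring paternal fraction (flagged /
#' evaluated maternal-homozygous loci) and heterozygosity:
#'
#' * an offspring is called **sexual** when its paternal fraction is at
#'   least `sexual_min`;
#' * it is called a **parthenogen** when its paternal fraction is at most
#'   `parthenogen_max` *and* its heterozygosity does not exceed
#'   `het_ratio_max` times the mother's (the automixis signature);
#' * anything else is **ambiguous**.
#'
#' Defaults come from the genotyping-error model rather than from any real
#' litter. Two error pathways inflate a true parthenogen's paternal
#' fraction: a uniform miscall at rate \eqn{\epsilon} plants a
#' non-maternal allele at a maternal-homozygous locus with probability
#' \eqn{2\epsilon/3}, and miscalls or dropout on the *mother* create
#' spuriously homozygous loci at which most offspring appear flagged —
#' together roughly \eqn{2\times(2\epsilon/3)} in expectation, with a
#' heavy upper tail at litter-scale locus counts. `parthenogen_max = 0.05`
#' sits above that floor for per-SNP error rates up to a few percent;
#' `sexual_min = 0.1` is comfortably above it yet far below the fractions
#' Mendelian litters produce, which track the sires' non-maternal allele
#' frequency (typically tens of percent, and necessarily at least the
#' litter's all-offspring conservative fraction).
#'
#' @param sexual_min Minimum paternal fraction to call an offspring sexual.
#' @param parthenogen_max Maximum paternal fraction to call a parthenogen;
#'   must be below `sexual_min`.
#' @param het_ratio_max Maximum offspring/mother heterozygosity ratio for a
#'   parthenogen call. Set to `Inf` to disable the heterozygosity check.
#' @return An object of class `mode_thresholds`.
#' @export
mode_thresholds <- function(sexual_min = 0.1, parthenogen_max = 0.05,
                            het_ratio_max = 0.9) {
  if (!is.numeric(sexual_min) || !is.numeric(parthenogen_max) ||
    sexual_min < 0 || sexual_min > 1 || parthenogen_max < 0 ||
    parthenogen_max > 1) {
    abort("fraction thresholds must lie in [0, 1]")
  }
  if (parthenogen_max >= sexual_min) {
    abort("parthenogen_max must be below sexual_min")
  }
  if (!is.numeric(het_ratio_max) || het_ratio_max < 0) {
    abort("het_ratio_max must be non-negative")
  }
  structure(
    list(
      sexual_min = sexual_min, parthenogen_max = parthenogen_max,
      het_ratio_max = het_ratio_max
    ),
    class = "mode_thresholds"
  )
}

#' Classify a litter as sperm storage versus parthenogenesis
#'
#' Turns a [scan_paternal_alleles()] result and per-sample heterozygosity
#' into per-offspring calls and a litter-level verdict. The litter is called
#' **LTSS** (long-term sperm storage, i.e. fathered) as soon as at least one
#' offspring is called sexual — a single offspring with a solid paternal
#' signal falsifies litter-wide parthenogenesis; **FP** when every offspring
#' is called a parthenogen; **ambiguous** otherwise.
#'
#' An all-male litter (from `meta`) is reported as corroborating FP evidence
#' — in ZW taxa parthenogens are male — but composition alone never drives
#' the call.
#'
#' @param scan A `paternal_scan` object.
#' @param het Output of [offspring_heterozygosity()] covering the offspring
#'   (and ideally the mother, which anchors the heterozygosity bound; if the
#'   mother is absent the heterozygosity check is skipped).
#' @param meta Optional sample metadata ([as_sample_meta]) supplying sex.
#' @param thresholds A [mode_thresholds()] object.
#' @return An object of class `mode_call`: `litter_call`, per-offspring
#'   `calls` tibble, `thresholds`, `all_male`, `n_infertile_ova` (from
#'   `meta` attributes, if present). [tidy()] returns the per-offspring
#'   calls, [glance()] a one-row litter summary.
#' @export
classify_mode <- function(scan, het, meta = NULL,
                          thresholds = mode_thresholds()) {
  stopifnot(inherits(scan, "paternal_scan"), inherits(thresholds, "mode_thresholds"))
  het_of <- setNames(het$heterozygosity, het$sample_id)
  mother_het <- unname(het_of[scan$mother_id])
  het_bound <- if (is.na(mother_het %||% NA)) {
    NA_real_
  } else {
    thresholds$het_ratio_max * mother_het
  }

  calls <- scan$per_offspring |>
    dplyr::mutate(
      heterozygosity = unname(het_of[.data$sample_id]),
      call = dplyr::case_when(
        is.na(.data$paternal_fraction) ~ "ambiguous",
        .data$paternal_fraction >= thresholds$sexual_min ~ "sexual",
        .data$paternal_fraction <= thresholds$parthenogen_max &
          (is.na(het_bound) | is.na(.data$heterozygosity) |
            .data$heterozygosity <= het_bound) ~ "parthenogen",
        TRUE ~ "ambiguous"
      )
    )
  litter_call <- if (any(calls$call == "sexual")) {
    "LTSS"
  } else if (all(calls$call == "parthenogen") && nrow(calls) > 0) {
    "FP"
  } else {
    "ambiguous"
  }

  all_male <- NA
  n_ova <- NA_integer_
  if (!is.null(meta)) {
    meta <- as_sample_meta(meta)
    sex <- meta$sex[match(scan$offspring_ids, meta$sample_id)]
    all_male <- if (anyNA(sex) || any(sex == "unknown")) NA else all(sex == "male")
    n_ova <- attr(meta, "n_infertile_ova") %||% NA_integer_
  }
  structure(
    list(
      litter_call = litter_call,
      calls = calls,
      thresholds = thresholds,
      mother_heterozygosity = unname(mother_het),
      all_male = all_male,
      n_infertile_ova = n_ova,
      mother_id = scan$mother_id
    ),
    class = "mode_call"
  )
}

#' @export
print.mode_call <- function(x, ...) {
  cat(sprintf("Litter call: %s\n", x$litter_call))
  cat(sprintf(
    "  thresholds: sexual >= %.3g, parthenogen <= %.3g, het ratio <= %.3g\n",
    x$thresholds$sexual_min, x$thresholds$parthenogen_max,
    x$thresholds$het_ratio_max
  ))
  if (!is.na(x$all_male)) {
    cat(sprintf(
      "  litter composition: %s%s\n",
      if (x$all_male) "all male" else "mixed sex",
      if (isTRUE(x$all_male)) " (corroborates FP in ZW taxa, never sufficient)" else ""
    ))
  }
  print(x$calls)
  invisible(x)
}

#' @method tidy mode_call
#' @export
tidy.mode_call <- function(x, ...) x$calls

#' @method glance mode_call
#' @export
glance.mode_call <- function(x, ...) {
  tibble(
    litter_call = x$litter_call,
    n_offspring = nrow(x$calls),
    n_sexual = sum(x$calls$call == "sexual"),
    n_parthenogen = sum(x$calls$call == "parthenogen"),
    n_ambiguous = sum(x$calls$call == "ambiguous"),
    all_male = x$all_male
  )
}

#' @method autoplot mode_call
#' @export
autoplot.mode_call <- function(object, ...) {
  d <- object$calls
  ggplot2::ggplot(
    d,
    ggplot2::aes(.data$paternal_fraction, .data$heterozygosity,
      colour = .data$call, label = .data$sample_id
    )
  ) +
    ggplot2::geom_vline(
      xintercept = c(
        object$thresholds$parthenogen_max, object$thresholds$sexual_min
      ),
      linetype = "dotted"
    ) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = "paternal fraction", y = "heterozygosity",
      title = sprintf("Reproductive-mode calls (litter: %s)", object$litter_call)
    )
}
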