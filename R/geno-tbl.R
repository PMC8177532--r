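#' Genotype tables
#'
#' The central container of the package is a *genotype table*: a long tibble
#' with one row per sample x locus cell and columns
#'
#' * `sample_id` (character),
#' * `locus_id` (character),
#' * `allele_1`, `allele_2` (integer allele codes; both `NA` when the
#'   genotype is missing).
#'
#' Genotypes are unordered pairs: `as_geno_tbl()` normalises each cell so
#' that `allele_1 <= allele_2`, which makes `(a,b)` and `(b,a)` identical.
#' Sample and locus order is the order of first appearance in the table; all
#' operations in the package preserve it.
#'
#' @param x A data frame with the four columns above. A half-missing cell
#'   (one allele `NA`) is coerced to fully missing with a warning.
#'
#' @return A tibble of class `geno_tbl`.
#' @examples
#' g <- as_geno_tbl(data.frame(
#'   sample_id = c("mom", "mom"), locus_id = c("L1", "L2"),
#'   allele_1 = c(2L, 1L), allele_2 = c(1L, NA)
#' ))
#' geno_loci(g)
#' @export
as_geno_tbl <- function(x) {
  x <- as_tibble(x)
  needed <- c("sample_id", "locus_id", "allele_1", "allele_2")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "genotype table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  x <- dplyr::select(x, dplyr::all_of(needed))
  x$sample_id <- as.character(x$sample_id)
  x$locus_id <- as.character(x$locus_id)
  x$allele_1 <- as.integer(x$allele_1)
  x$allele_2 <- as.integer(x$allele_2)

  half <- xor(is.na(x$allele_1), is.na(x$allele_2))
  if (any(half)) {
    warn(sprintf(
      "%d half-missing genotype(s) coerced to missing", sum(half)
    ))
    x$allele_1[half] <- NA_integer_
    x$allele_2[half] <- NA_integer_
  }
  swap <- !is.na(x$allele_1) & x$allele_1 > x$allele_2
  if (any(swap)) {
    tmp <- x$allele_1[swap]
    x$allele_1[swap] <- x$allele_2[swap]
    x$allele_2[swap] <- tmp
  }
  if (anyDuplicated(paste(x$sample_id, x$locus_id, sep = "\r")) > 0) {
    abort("duplicate (sample_id, locus_id) cells in genotype table")
  }
  class(x) <- c("geno_tbl", class(tibble()))
  x
}

#' @rdname as_geno_tbl
#' @export
is_geno_tbl <- function(x) inherits(x, "geno_tbl")

#' @rdname as_geno_tbl
#' @export
geno_samples <- function(x) unique(as.character(x$sample_id))

#' @rdname as_geno_tbl
#' @export
geno_loci <- function(x) unique(as.character(x$locus_id))

#' @export
print.geno_tbl <- function(x, ...) {
  n_s <- length(geno_samples(x))
  n_l <- length(geno_loci(x))
  pct <- if (nrow(x) > 0) 100 * mean(is.na(x$allele_1)) else 0
  cat(sprintf(
    "# Genotype table: %d sample(s) x %d locus/loci, %.1f%% missing\n",
    n_s, n_l, pct
  ))
  print(as_tibble(unclass_geno(x)), ...)
  invisible(x)
}

unclass_geno <- function(x) {
  class(x) <- setdiff(class(x), "geno_tbl")
  x
}

## Wide (allele-matrix) view used internally for vectorised math. Row/col
## order follows first appearance in the table, regardless of row order.
as_geno_matrices <- function(g) {
  samples <- geno_samples(g)
  loci <- geno_loci(g)
  a1 <- matrix(NA_integer_, length(samples), length(loci),
    dimnames = list(samples, loci)
  )
  a2 <- a1
  idx <- cbind(match(g$sample_id, samples), match(g$locus_id, loci))
  a1[idx] <- g$allele_1
  a2[idx] <- g$allele_2
  list(a1 = a1, a2 = a2, samples = samples, loci = loci)
}

geno_from_matrices <- function(a1, a2) {
  samples <- rownames(a1)
  loci <- colnames(a1)
  as_geno_tbl(tibble(
    sample_id = rep(samples, each = length(loci)),
    locus_id = rep(loci, times = length(samples)),
    allele_1 = as.integer(t(a1)),
    allele_2 = as.integer(t(a2))
  ))
}

#' Sample metadata tables
#'
#' Litter analyses carry a small metadata table alongside the genotypes: one
#' row per sample with `sample_id`, `role` (`"mother"` or `"offspring"`) and
#' `sex` (`"male"`, `"female"` or `"unknown"`). Exactly one sample may have
#' the mother role.
#'
#' @param x A data frame with columns `sample_id`, `role`, `sex`.
#' @return A validated tibble.
#' @export
as_sample_meta <- function(x) {
  x <- as_tibble(x)
  needed <- c("sample_id", "role", "sex")
  if (!all(needed %in% names(x))) {
    abort("sample metadata needs columns sample_id, role, sex")
  }
  x$sample_id <- as.character(x$sample_id)
  if (!all(x$role %in% c("mother", "offspring"))) {
    abort("role must be 'mother' or 'offspring'")
  }
  if (!all(x$sex %in% c("male", "female", "unknown"))) {
    abort("sex must be 'male', 'female' or 'unknown'")
  }
  if (sum(x$role == "mother") != 1) {
    abort("exactly one sample must have role 'mother'")
  }
  x
}

#' @rdname as_sample_meta
#' @param path File path for the JSON sidecar.
#' @export
read_sample_meta <- function(path) {
  as_sample_meta(as_tibble(jsonlite::fromJSON(path)))
}

#' @rdname as_sample_meta
#' @param meta A metadata tibble.
#' @export
write_sample_meta <- function(meta, path) {
  meta <- as_sample_meta(meta)
  jsonlite::write_json(meta, path, dataframe = "rows", auto_unbox = FALSE)
  invisible(path)
}
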