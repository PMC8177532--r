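#' Structure-format genotype files
#'
#' Reads and writes the plain-text Structure genotype format used throughout
#' RAD-seq population genetics: whitespace-delimited integer allele codes,
#' one individual per pair of rows (each row carrying one allele per locus)
#' or, in the one-row dialect, one individual per row with two adjacent
#' columns per locus. A configurable sentinel (conventionally -9) marks
#' missing genotypes.
#'
#' @param path File path.
#' @param dialect A [structure_dialect()] describing the layout.
#' @return `read_structure()` returns a [geno_tbl][as_geno_tbl] genotype
#'   table; `write_structure()` invisibly returns `path`.
#' @examples
#' g <- as_geno_tbl(data.frame(
#'   sample_id = rep(c("a", "b"), each = 2),
#'   locus_id = rep(c("L1", "L2"), 2),
#'   allele_1 = c(1L, 1L, NA, 2L), allele_2 = c(2L, 1L, NA, 2L)
#' ))
#' f <- tempfile()
#' write_structure(g, f)
#' read_structure(f)
#' @name structure_io
NULL

#' @rdname structure_io
#' @param layout `"two_row"` (two rows per individual, one allele column per
#'   locus) or `"one_row"` (one row, two columns per locus).
#' @param header Whether the first line lists locus names.
#' @param missing Integer sentinel for missing alleles.
#' @export
structure_dialect <- function(layout = c("two_row", "one_row"),
                              header = FALSE, missing = -9L) {
  layout <- match.arg(layout)
  stopifnot(is.logical(header), length(header) == 1)
  missing <- as.integer(missing)
  stopifnot(length(missing) == 1, !is.na(missing))
  structure(
    list(layout = layout, header = header, missing = missing),
    class = "structure_dialect"
  )
}

#' @rdname structure_io
#' @export
read_structure <- function(path, dialect = structure_dialect()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  stopifnot(inherits(dialect, "structure_dialect"))
  raw <- readLines(path)
  keep <- which(!grepl("^\\s*$", raw))
  lines <- raw[keep]
  tokens <- strsplit(trimws(lines), "[ \t]+")

  locus_ids <- NULL
  if (dialect$header) {
    if (length(tokens) == 0) abort("header requested but file is empty")
    locus_ids <- tokens[[1]]
    tokens <- tokens[-1]
    keep <- keep[-1]
  }
  per_locus <- if (dialect$layout == "two_row") 1L else 2L

  n_loci <- if (!is.null(locus_ids)) {
    length(locus_ids)
  } else if (length(tokens) > 0) {
    (length(tokens[[1]]) - 1L) %/% per_locus
  } else {
    0L
  }
  if (is.null(locus_ids)) {
    locus_ids <- if (n_loci > 0) sprintf("locus_%d", seq_len(n_loci)) else character()
  }

  expected <- 1L + per_locus * n_loci
  parse_row <- function(i) {
    tk <- tokens[[i]]
    if (length(tk) != expected) {
      abort(sprintf(
        "line %d: expected %d fields, found %d", keep[i], expected, length(tk)
      ))
    }
    al <- suppressWarnings(as.integer(tk[-1]))
    if (anyNA(al)) {
      abort(sprintf(
        "line %d: non-integer allele token '%s'",
        keep[i], tk[-1][which(is.na(al))[1]]
      ))
    }
    list(id = tk[1], alleles = al)
  }
  rows <- lapply(seq_along(tokens), parse_row)

  if (length(rows) == 0) {
    cells <- tibble(
      sample_id = character(), locus_id = character(),
      allele_1 = integer(), allele_2 = integer()
    )
  } else if (dialect$layout == "two_row") {
    if (length(rows) %% 2 != 0) {
      abort("two-row dialect: odd number of genotype rows")
    }
    ind <- seq(1, length(rows), by = 2)
    cells <- purrr::map_dfr(ind, function(i) {
      r1 <- rows[[i]]
      r2 <- rows[[i + 1]]
      if (r1$id != r2$id) {
        abort(sprintf(
          "line %d: row pair has mismatched sample ids '%s' / '%s'",
          keep[i + 1], r1$id, r2$id
        ))
      }
      tibble(
        sample_id = r1$id, locus_id = locus_ids,
        allele_1 = r1$alleles, allele_2 = r2$alleles
      )
    })
  } else {
    cells <- purrr::map_dfr(rows, function(r) {
      tibble(
        sample_id = r$id, locus_id = locus_ids,
        allele_1 = r$alleles[seq(1, length(r$alleles), by = 2)],
        allele_2 = r$alleles[seq(2, length(r$alleles), by = 2)]
      )
    })
  }
  if (nrow(cells) > 0) {
    miss <- cells$allele_1 == dialect$missing | cells$allele_2 == dialect$missing
    cells$allele_1[miss] <- NA_integer_
    cells$allele_2[miss] <- NA_integer_
  }
  as_geno_tbl(cells)
}

#' @rdname structure_io
#' @param g A genotype table.
#' @export
write_structure <- function(g, path, dialect = structure_dialect()) {
  g <- as_geno_tbl(g)
  stopifnot(inherits(dialect, "structure_dialect"))
  m <- as_geno_matrices(g)
  a1 <- m$a1
  a2 <- m$a2
  a1[is.na(a1)] <- dialect$missing
  a2[is.na(a2)] <- dialect$missing

  out <- character()
  if (dialect$header) out <- paste(m$loci, collapse = " ")
  for (i in seq_along(m$samples)) {
    if (dialect$layout == "two_row") {
      out <- c(
        out,
        paste(c(m$samples[i], a1[i, ]), collapse = " "),
        paste(c(m$samples[i], a2[i, ]), collapse = " ")
      )
    } else {
      inter <- as.vector(rbind(a1[i, ], a2[i, ]))
      out <- c(out, paste(c(m$samples[i], inter), collapse = " "))
    }
  }
  writeLines(out, path)
  invisible(path)
}
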