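#' Restriction enzymes
#'
#' A restriction enzyme is described by its recognition sequence and the
#' 0-based cut offset within it (position of the cut measured from the 5'
#' end of the recognition site on the strand carrying it). The two built-ins
#' are the classic ddRAD pair: PstI (CTGCA^G, offset 5) and MspI (C^CGG,
#' offset 1); both sites are palindromic.
#'
#' @param name Enzyme name (used to label fragment ends). `enzyme("PstI")`
#'   and `enzyme("MspI")` return the built-ins.
#' @param site Recognition sequence over A/C/G/T.
#' @param cut_offset Integer in \[0, nchar(site)\].
#' @return An object of class `restriction_enzyme`.
#' @examples
#' enzyme("PstI")
#' enzyme("EcoRI", "GAATTC", 1)
#' @export
enzyme <- function(name, site = NULL, cut_offset = NULL) {
  builtin <- list(
    PstI = list(site = "CTGCAG", cut_offset = 5L),
    MspI = list(site = "CCGG", cut_offset = 1L)
  )
  if (is.null(site)) {
    if (!name %in% names(builtin)) {
      abort(sprintf(
        "unknown enzyme '%s'; supply site and cut_offset explicitly", name
      ))
    }
    site <- builtin[[name]]$site
    cut_offset <- builtin[[name]]$cut_offset
  }
  site <- toupper(site)
  if (!grepl("^[ACGT]+$", site)) {
    abort("recognition site must be over A/C/G/T")
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0 || cut_offset > nchar(site)) {
    abort("cut_offset must lie within the recognition site")
  }
  structure(
    list(name = name, site = site, cut_offset = cut_offset),
    class = "restriction_enzyme"
  )
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' In-silico double digestion
#'
#' Locates every occurrence of the enzymes' recognition sites and returns
#' the fragments between consecutive cut positions, each end labelled with
#' the enzyme that produced it (or `"terminus"` for a sequence end).
#' Palindromic sites are scanned on the forward strand only (a reverse scan
#' would double-count); non-palindromic sites are scanned on both strands
#' with the cut offset mirrored for reverse-strand occurrences. Coordinates
#' are 0-based half-open (BED convention); zero-length fragments (cuts at a
#' sequence boundary) are not emitted.
#'
#' @param seqs A named character vector of DNA sequences or a
#'   `Biostrings::DNAStringSet`.
#' @param enzymes List of [enzyme()] objects (default PstI + MspI).
#' @param ambiguity `"skip"` tolerates non-ACGT letters (sites simply never
#'   match across them); `"error"` rejects such sequences.
#' @return A tibble of class `fragment_set` with columns `seq_id`, `start`,
#'   `end`, `length`, `end5`, `end3`.
#' @examples
#' digest_sequences(c(chr = "AACTGCAGAA"), list(enzyme("PstI")))
#' @export
digest_sequences <- function(seqs,
                             enzymes = list(enzyme("PstI"), enzyme("MspI")),
                             ambiguity = c("skip", "error")) {
  ambiguity <- match.arg(ambiguity)
  if (inherits(seqs, "DNAStringSet")) {
    seqset <- seqs
  } else {
    seqs <- toupper(unlist(seqs))
    if (is.null(names(seqs)) || any(names(seqs) == "")) {
      names(seqs) <- paste0("seq_", seq_along(seqs))
    }
    seqset <- Biostrings::DNAStringSet(seqs)
  }
  if (inherits(enzymes, "restriction_enzyme")) enzymes <- list(enzymes)
  stopifnot(all(vapply(enzymes, inherits, logical(1), "restriction_enzyme")))

  frags <- purrr::map_dfr(seq_along(seqset), function(si) {
    subject <- seqset[[si]]
    seq_id <- names(seqset)[si]
    n <- length(subject)
    if (ambiguity == "error" &&
      sum(Biostrings::alphabetFrequency(subject)[c("A", "C", "G", "T")]) < n) {
      abort(sprintf("sequence '%s' contains ambiguity codes", seq_id))
    }
    cuts <- purrr::map_dfr(enzymes, function(ez) {
      len <- nchar(ez$site)
      fwd <- Biostrings::start(Biostrings::matchPattern(ez$site, subject))
      pos <- (fwd - 1L) + ez$cut_offset
      rc <- revcomp(ez$site)
      if (rc != ez$site) {
        rev <- Biostrings::start(Biostrings::matchPattern(rc, subject))
        pos <- c(pos, (rev - 1L) + (len - ez$cut_offset))
      }
      tibble(pos = as.integer(pos), enzyme = ez$name)
    })
    # interior cuts only; on position ties keep the first enzyme listed
    cuts <- cuts[cuts$pos > 0 & cuts$pos < n, , drop = FALSE]
    cuts <- cuts[!duplicated(cuts$pos), , drop = FALSE]
    cuts <- cuts[order(cuts$pos), , drop = FALSE]

    bounds <- c(0L, cuts$pos, n)
    labels <- c("terminus", cuts$enzyme, "terminus")
    k <- length(bounds) - 1L
    tibble(
      seq_id = seq_id,
      start = bounds[seq_len(k)],
      end = bounds[seq_len(k) + 1L],
      length = bounds[seq_len(k) + 1L] - bounds[seq_len(k)],
      end5 = labels[seq_len(k)],
      end3 = labels[seq_len(k) + 1L]
    )
  })
  new_fragment_set(frags)
}

new_fragment_set <- function(x, window_center = NA_real_,
                             window_halfwidth = NA_real_) {
  x <- as_tibble(x)
  attr(x, "window_center") <- window_center
  attr(x, "window_halfwidth") <- window_halfwidth
  class(x) <- unique(c("fragment_set", class(tibble())))
  x
}

#' @rdname digest_sequences
#' @param path Path to a (multi-)FASTA file.
#' @param ... Passed on to `digest_sequences()`.
#' @export
digest_fasta <- function(path, ...) {
  digest_sequences(Biostrings::readDNAStringSet(path), ...)
}

#' Size-select ddRAD fragments
#'
#' Retains fragments whose length lies in the inclusive window
#' `[center - halfwidth, center + halfwidth]` — the in-silico analogue of
#' gel-based size selection. With `require_mixed_ends = TRUE` only
#' fragments cut by two *different* enzymes (no sequence-terminus ends) are
#' kept: on a double-digest library these are the fragments that acquire
#' both adapters and get sequenced.
#'
#' @param fragments A `fragment_set` from [digest_sequences()].
#' @param center,halfwidth Window centre and half-width in bp (defaults 300
#'   and 50, i.e. \[250, 350\]).
#' @param require_mixed_ends Keep only fragments with two distinct enzyme
#'   ends.
#' @return A filtered `fragment_set` carrying the window in its attributes.
#' @export
select_ddrad <- function(fragments, center = 300, halfwidth = 50,
                         require_mixed_ends = FALSE) {
  stopifnot(is.numeric(center), is.numeric(halfwidth), center >= 0, halfwidth >= 0)
  keep <- fragments$length >= center - halfwidth &
    fragments$length <= center + halfwidth
  if (require_mixed_ends) {
    keep <- keep & fragments$end5 != "terminus" & fragments$end3 != "terminus" &
      fragments$end5 != fragments$end3
  }
  new_fragment_set(fragments[keep, , drop = FALSE], center, halfwidth)
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf(
    "# Fragment set: %d fragment(s) on %d sequence(s)",
    nrow(x), length(unique(x$seq_id))
  ))
  wc <- attr(x, "window_center")
  if (!is.na(wc)) {
    cat(sprintf(
      ", size window %g +/- %g bp", wc, attr(x, "window_halfwidth")
    ))
  }
  cat("\n")
  print(as_tibble(unclass_fragments(x)), ...)
  invisible(x)
}

unclass_fragments <- function(x) {
  class(x) <- setdiff(class(x), "fragment_set")
  x
}

#' @method glance fragment_set
#' @export
glance.fragment_set <- function(x, ...) {
  tibble(
    n_fragments = nrow(x),
    n_sequences = length(unique(x$seq_id)),
    n_mixed_ends = sum(
      x$end5 != "terminus" & x$end3 != "terminus" & x$end5 != x$end3
    ),
    mean_length = mean(x$length),
    median_length = stats::median(x$length)
  )
}

#' @method autoplot fragment_set
#' @export
autoplot.fragment_set <- function(object, binwidth = 25, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$length)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40") +
    ggplot2::labs(
      x = "fragment length (bp)", y = "count",
      title = "In-silico digest fragment lengths"
    )
  wc <- attr(object, "window_center")
  if (!is.na(wc)) {
    hw <- attr(object, "window_halfwidth")
    p <- p + ggplot2::geom_vline(
      xintercept = c(wc - hw, wc + hw), linetype = "dashed",
      colour = "firebrick"
    )
  }
  p
}

#' Write fragments as BED
#'
#' BED-style TSV export of a fragment set (0-based half-open coordinates;
#' the name field carries the two end labels).
#'
#' @param fragments A `fragment_set`.
#' @param path Output path.
#' @export
write_fragments_bed <- function(fragments, path) {
  bed <- data.frame(
    chrom = fragments$seq_id,
    chromStart = fragments$start,
    chromEnd = fragments$end,
    name = paste(fragments$end5, fragments$end3, sep = "/"),
    score = fragments$length,
    strand = "+"
  )
  write.table(bed, path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
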