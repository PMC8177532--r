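# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths: keyed scalar lookups, explicit loops and explicit
# enumeration, so that agreement is a real cross-check.

# random genotype table over allele codes `alleles`, with missingness
random_geno <- function(n_samples, n_loci, missing = 0.2, alleles = 1:2,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  samples <- c("mother", sprintf("kid_%02d", seq_len(n_samples - 1)))
  loci <- sprintf("L%03d", seq_len(n_loci))
  n <- n_samples * n_loci
  a1 <- sample(alleles, n, replace = TRUE)
  a2 <- sample(alleles, n, replace = TRUE)
  miss <- runif(n) < missing
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  as_geno_tbl(data.frame(
    sample_id = rep(samples, each = n_loci),
    locus_id = rep(loci, times = n_samples),
    allele_1 = pmin(a1, a2), allele_2 = pmax(a1, a2)
  ))
}

# naive triple-loop paternal-allele scan
oracle_scan <- function(g, mother_id, offspring_ids,
                        policy = c("strict", "evaluated_only")) {
  policy <- match.arg(policy)
  key <- paste(g$sample_id, g$locus_id, sep = "\r")
  a1 <- setNames(g$allele_1, key)
  a2 <- setNames(g$allele_2, key)
  loci <- unique(g$locus_id)

  hom <- character()
  for (L in loci) {
    k <- paste(mother_id, L, sep = "\r")
    if (!is.na(a1[k]) && a1[k] == a2[k]) hom <- c(hom, L)
  }
  flags <- matrix(NA, length(offspring_ids), length(hom),
    dimnames = list(offspring_ids, hom)
  )
  for (L in hom) {
    ma <- a1[paste(mother_id, L, sep = "\r")]
    for (o in offspring_ids) {
      k <- paste(o, L, sep = "\r")
      if (!is.na(a1[k])) {
        flags[o, L] <- (a1[k] != ma) || (a2[k] != ma)
      }
    }
  }
  conservative <- 0L
  liberal <- 0L
  for (L in hom) {
    col <- flags[, L]
    ok <- if (policy == "strict") {
      !anyNA(col) && all(col)
    } else {
      any(!is.na(col)) && all(col[!is.na(col)])
    }
    if (ok) conservative <- conservative + 1L
    if (isTRUE(any(col, na.rm = TRUE))) liberal <- liberal + 1L
  }
  list(
    hom = hom, flags = flags,
    conservative = conservative, liberal = liberal
  )
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# naive string-scan digestion (substring comparison position by position)
oracle_digest <- function(seq, enzymes) {
  n <- nchar(seq)
  pos <- integer()
  enz <- character()
  for (ez in enzymes) {
    for (pat_off in list(
      list(pat = ez$site, off = ez$cut_offset),
      if (oracle_revcomp(ez$site) != ez$site) {
        list(pat = oracle_revcomp(ez$site), off = nchar(ez$site) - ez$cut_offset)
      }
    )) {
      if (is.null(pat_off)) next
      L <- nchar(pat_off$pat)
      if (L > n) next
      for (s in 1:(n - L + 1)) {
        if (substr(seq, s, s + L - 1) == pat_off$pat) {
          pos <- c(pos, s - 1 + pat_off$off)
          enz <- c(enz, ez$name)
        }
      }
    }
  }
  inside <- pos > 0 & pos < n
  pos <- pos[inside]
  enz <- enz[inside]
  dup <- duplicated(pos)
  pos <- pos[!dup]
  enz <- enz[!dup]
  o <- order(pos)
  bounds <- c(0L, pos[o], n)
  labs <- c("terminus", enz[o], "terminus")
  k <- length(bounds) - 1L
  data.frame(
    start = bounds[seq_len(k)], end = bounds[seq_len(k) + 1],
    length = bounds[seq_len(k) + 1] - bounds[seq_len(k)],
    end5 = labs[seq_len(k)], end3 = labs[seq_len(k) + 1],
    stringsAsFactors = FALSE
  )
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# exhaustive enumeration of the per-locus full-sib / half-sib likelihood
# ratio: loops over father genotypes, the father pair (half-sib), each
# parental allele transmission, and the observation channel
oracle_sib_locus_ratio <- function(f2, m, oi, oj, eps) {
  genos <- list(c(0L, 0L), c(0L, 1L), c(1L, 1L)) # counts of second allele
  hwe <- c((1 - f2)^2, 2 * f2 * (1 - f2), f2^2)
  mom <- genos[[m + 1]]
  p_obs <- function(obs, true) (1 - eps) * (obs == true) + eps / 3
  p_off <- function(obs, gf) {
    tot <- 0
    for (ma in mom) {
      for (pa in genos[[gf + 1]]) {
        tot <- tot + 0.25 * p_obs(obs, ma + pa)
      }
    }
    tot
  }
  l_fs <- 0
  for (gf in 0:2) l_fs <- l_fs + hwe[gf + 1] * p_off(oi, gf) * p_off(oj, gf)
  l_hs <- 0
  for (gf1 in 0:2) {
    for (gf2 in 0:2) {
      l_hs <- l_hs + hwe[gf1 + 1] * hwe[gf2 + 1] * p_off(oi, gf1) * p_off(oj, gf2)
    }
  }
  l_fs / l_hs
}

# single-locus genotype table + matching frequency table for sibship tests;
# genotypes given as counts of allele 2
sib_single_locus <- function(m, oi, oj, f2) {
  decode <- function(cnt) c(allele_1 = if (cnt == 2) 2L else 1L,
                            allele_2 = if (cnt >= 1) 2L else 1L)
  gm <- decode(m); gi <- decode(oi); gj <- decode(oj)
  g <- as_geno_tbl(data.frame(
    sample_id = c("mother", "o1", "o2"),
    locus_id = "L1",
    allele_1 = c(gm[1], gi[1], gj[1]),
    allele_2 = c(gm[2], gi[2], gj[2])
  ))
  freqs <- tibble::tibble(
    locus_id = "L1", allele_a = 1L, allele_b = 2L,
    freq_a = 1 - f2, maf = min(f2, 1 - f2), n_obs = 6L, n_alleles = 2L
  )
  list(g = g, freqs = freqs)
}

# hand-built constant-genotype parents for Mendelian closed-form tests
const_parent <- function(n_loci, a, b) {
  tibble::tibble(
    locus_id = sprintf("locus_%d", seq_len(n_loci)),
    allele_1 = pmin(a, b), allele_2 = pmax(a, b)
  )
}
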