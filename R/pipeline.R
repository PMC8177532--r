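#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis: either an input block
#' (Structure file + metadata sidecar) or a simulation block (a
#' [litter_sim_config()]), the locus filters, scan and classifier settings,
#' and the sibship stage. Exactly one of `input` and `simulate` must be
#' given.
#'
#' The *replication* settings used for a males-only single-litter study are
#' `filters = list(r = 1, maf_threshold = 0, maf_mode = "ge")`,
#' `scan = list(males_only = TRUE, missing_policy = "strict")` and
#' `sibship = list(error_rate = 0.05, llr_threshold = 0)`.
#'
#' @param input `NULL` or a list with `structure` (path), `meta` (path to a
#'   JSON metadata sidecar) and optionally `dialect` (a
#'   [structure_dialect()]).
#' @param simulate `NULL` or a [litter_sim_config()].
#' @param filters List: `r` (completeness fraction, default 1),
#'   `maf_threshold` (default 0, i.e. off), `maf_mode` (`"ge"`/`"eq"`).
#' @param scan List: `males_only` (default `FALSE`), `missing_policy`.
#' @param thresholds A [mode_thresholds()].
#' @param sibship List: `error_rate` (default 0.05), `llr_threshold`
#'   (default 0), `enabled` (default `TRUE`).
#' @param seed Optional integer seed (forwarded to the simulation block when
#'   that block has none).
#' @param out_dir Default output directory for [run_pipeline()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL,
                            filters = list(), scan = list(),
                            thresholds = mode_thresholds(),
                            sibship = list(), seed = NULL, out_dir = NULL) {
  if (is.null(input) == is.null(simulate)) {
    abort("exactly one of 'input' and 'simulate' must be given")
  }
  if (!is.null(input)) {
    if (!is.list(input) || is.null(input$structure) || is.null(input$meta)) {
      abort("input block needs $structure and $meta paths")
    }
    input$dialect <- input$dialect %||% structure_dialect()
  }
  if (!is.null(simulate)) {
    stopifnot(inherits(simulate, "litter_sim_config"))
    if (!is.null(seed) && is.null(simulate$seed)) simulate$seed <- as.integer(seed)
  }
  filters <- utils::modifyList(
    list(r = 1, maf_threshold = 0, maf_mode = "ge"), filters
  )
  scan <- utils::modifyList(
    list(males_only = FALSE, missing_policy = "strict"), scan
  )
  sibship <- utils::modifyList(
    list(error_rate = 0.05, llr_threshold = 0, enabled = TRUE), sibship
  )
  stopifnot(inherits(thresholds, "mode_thresholds"))
  structure(
    list(
      input = input, simulate = simulate, filters = filters, scan = scan,
      thresholds = thresholds, sibship = sibship, seed = seed,
      out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The document maps 1:1 onto [pipeline_config()]: top-level keys `input`
#' or `simulate`, plus optional `filters`, `scan`, `thresholds`, `sibship`,
#' `seed`, `out_dir`. The `simulate` block holds [litter_sim_config()]
#' arguments; `thresholds` holds [mode_thresholds()] arguments.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  sim <- if (!is.null(doc$simulate)) do.call(litter_sim_config, doc$simulate)
  thr <- if (!is.null(doc$thresholds)) {
    do.call(mode_thresholds, doc$thresholds)
  } else {
    mode_thresholds()
  }
  pipeline_config(
    input = doc$input, simulate = sim,
    filters = doc$filters %||% list(), scan = doc$scan %||% list(),
    thresholds = thr, sibship = doc$sibship %||% list(),
    seed = doc$seed, out_dir = doc$out_dir
  )
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the end-to-end litter analysis
#'
#' simulate/load -> filter -> paternal-allele scan -> heterozygosity ->
#' reproductive-mode call -> sibship partition, with machine-readable
#' reports written to `out_dir`: `manifest.json` (config echo, package
#' version, seed — written first so failures are diagnosable),
#' `scan_report.json`, `mode_call.json`, `sibship.json`, `flags.tsv` (per
#' locus, per offspring) and `summary.txt`. Identical configuration and
#' seed reproduce identical reports (manifest timestamp aside).
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed); overrides the
#'   configuration's `out_dir`. `NULL` skips report writing.
#' @return Invisibly, a list with `genotypes`, `meta`, `scan`, `het`,
#'   `mode`, `sibship` (or `NULL`), `paths`.
#' @export
run_pipeline <- function(cfg, out_dir = cfg$out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(
      package = "sirescan",
      version = as.character(utils::packageVersion("sirescan")),
      seed = cfg$seed %||% cfg$simulate$seed,
      timestamp = format(Sys.time(), tz = "UTC"),
      config = config_echo(cfg)
    )
    paths$manifest <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, paths$manifest,
      auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA
    )
  }

  if (!is.null(cfg$simulate)) {
    log_stage("simulate", "mode=%s, %d loci, %d offspring",
      cfg$simulate$mode, cfg$simulate$n_loci, cfg$simulate$n_offspring
    )
    sim <- simulate_litter(cfg$simulate)
    g <- sim$genotypes
    meta <- sim$meta
  } else {
    log_stage("load", "reading %s", cfg$input$structure)
    g <- read_structure(cfg$input$structure, cfg$input$dialect)
    meta <- read_sample_meta(cfg$input$meta)
  }
  mother_id <- meta$sample_id[meta$role == "mother"]

  log_stage("filter", "r=%g, MAF %s %g",
    cfg$filters$r, cfg$filters$maf_mode, cfg$filters$maf_threshold
  )
  g <- filter_complete_loci(g, cfg$filters$r)
  if (cfg$filters$maf_threshold > 0 || cfg$filters$maf_mode == "eq") {
    g <- filter_maf(g, cfg$filters$maf_threshold, cfg$filters$maf_mode)
  }
  log_stage("filter", "%d loci retained", length(geno_loci(g)))

  off_meta <- meta[meta$role == "offspring", , drop = FALSE]
  offspring <- if (isTRUE(cfg$scan$males_only)) {
    off_meta$sample_id[off_meta$sex == "male"]
  } else {
    off_meta$sample_id
  }
  offspring <- intersect(offspring, geno_samples(g))
  log_stage("scan", "%d offspring, policy=%s",
    length(offspring), cfg$scan$missing_policy
  )
  scan <- scan_paternal_alleles(
    g, mother_id, offspring,
    missing_policy = cfg$scan$missing_policy
  )
  het <- offspring_heterozygosity(g, c(mother_id, offspring))
  mode <- classify_mode(scan, het, meta, cfg$thresholds)
  log_stage("classify", "litter call: %s", mode$litter_call)

  sib <- NULL
  if (isTRUE(cfg$sibship$enabled) && length(offspring) >= 2) {
    sib <- partition_sibships(
      g, mother_id, offspring,
      error_rate = cfg$sibship$error_rate,
      llr_threshold = cfg$sibship$llr_threshold
    )
    log_stage("sibship", "minimum sires: %d", sib$n_sires_min)
  } else if (isTRUE(cfg$sibship$enabled)) {
    log_stage("sibship", "skipped (fewer than two offspring)")
  }

  if (!is.null(out_dir)) {
    paths$scan <- file.path(out_dir, "scan_report.json")
    jsonlite::write_json(
      c(
        as.list(glance(scan)),
        list(per_offspring = scan$per_offspring,
             conservative_loci = scan$conservative_loci)
      ),
      paths$scan, auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
    paths$mode <- file.path(out_dir, "mode_call.json")
    jsonlite::write_json(
      list(
        litter_call = mode$litter_call,
        all_male = mode$all_male,
        thresholds = unclass(mode$thresholds),
        calls = mode$calls
      ),
      paths$mode, auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA
    )
    if (!is.null(sib)) {
      paths$sibship <- file.path(out_dir, "sibship.json")
      jsonlite::write_json(
        list(
          n_sires_min = sib$n_sires_min,
          clusters = sib$clusters,
          pairwise = sib$pairwise,
          error_rate = sib$error_rate,
          llr_threshold = sib$llr_threshold
        ),
        paths$sibship, auto_unbox = TRUE, pretty = TRUE, digits = NA
      )
    }
    paths$flags <- file.path(out_dir, "flags.tsv")
    write.table(
      tidy(scan), paths$flags,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    paths$summary <- file.path(out_dir, "summary.txt")
    withr::with_output_sink(paths$summary, {
      print(scan)
      print(mode)
      if (!is.null(sib)) print(sib)
    })
  }
  invisible(list(
    genotypes = g, meta = meta, scan = scan, het = het, mode = mode,
    sibship = sib, paths = paths
  ))
}

config_echo <- function(cfg) {
  list(
    input = if (!is.null(cfg$input)) {
      list(
        structure = cfg$input$structure, meta = cfg$input$meta,
        dialect = unclass(cfg$input$dialect)
      )
    },
    simulate = if (!is.null(cfg$simulate)) unclass(cfg$simulate),
    filters = cfg$filters,
    scan = cfg$scan,
    thresholds = unclass(cfg$thresholds),
    sibship = cfg$sibship,
    out_dir = cfg$out_dir
  )
}

#' Power of the litter-level classifier across simulation settings
#'
#' For each configuration in `configs`, simulates `replicates` litters,
#' runs the scan and classifier, and reports the fraction of replicates
#' whose litter call matches the generating mode together with the mean
#' conservative fraction, each with its Monte-Carlo standard error. Answers
#' design questions of the form "how many loci distinguish sperm storage
#' from parthenogenesis at genotyping-error rate epsilon?".
#'
#' @param configs A list of [litter_sim_config()] objects (a single config
#'   is accepted).
#' @param replicates Replicates per configuration.
#' @param thresholds A [mode_thresholds()].
#' @param seed Base seed; replicate r of configuration i runs with seed
#'   `seed + 1000 * i + r` (modulo the integer range).
#' @return A tibble with one row per configuration: `mode`, `n_loci`,
#'   `n_offspring`, error rates, `correct_fraction`, `correct_se`,
#'   `mean_conservative_fraction`, `conservative_se`, `n_replicates`.
#' @export
power_curve <- function(configs, replicates = 20,
                        thresholds = mode_thresholds(), seed = NULL) {
  if (inherits(configs, "litter_sim_config")) configs <- list(configs)
  stopifnot(
    length(configs) > 0,
    all(vapply(configs, inherits, logical(1), "litter_sim_config")),
    replicates >= 1
  )
  purrr::map_dfr(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    res <- purrr::map_dfr(seq_len(replicates), function(r) {
      cfg_r <- cfg
      if (!is.null(seed)) {
        cfg_r$seed <- as.integer((seed + 1000 * i + r) %% 2147483629)
      }
      sim <- simulate_litter(cfg_r)
      out <- suppressWarnings(run_scan_classify(sim, thresholds))
      tibble(
        correct = out$call == expected_call(cfg$mode),
        cons_frac = out$cons_frac
      )
    })
    tibble(
      mode = cfg$mode,
      n_loci = cfg$n_loci,
      n_offspring = cfg$n_offspring,
      dropout_rate = cfg$dropout_rate,
      miscall_rate = cfg$miscall_rate,
      missing_rate = cfg$missing_rate,
      correct_fraction = mean(res$correct),
      correct_se = stats::sd(res$correct) / sqrt(replicates),
      mean_conservative_fraction = mean(res$cons_frac, na.rm = TRUE),
      conservative_se = stats::sd(res$cons_frac, na.rm = TRUE) / sqrt(replicates),
      n_replicates = replicates
    )
  })
}

expected_call <- function(mode) if (mode == "ltss") "LTSS" else "FP"

run_scan_classify <- function(sim, thresholds) {
  offspring <- sim$meta$sample_id[sim$meta$role == "offspring"]
  scan <- scan_paternal_alleles(sim$genotypes, "mother", offspring)
  het <- offspring_heterozygosity(sim$genotypes)
  mode <- classify_mode(scan, het, sim$meta, thresholds)
  n_hom <- length(scan$loci)
  list(
    call = mode$litter_call,
    cons_frac = if (n_hom > 0) scan$conservative_count / n_hom else NA_real_
  )
}
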