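config_defaults <- list(
  screen_direction = "enrichment",
  trim = list(error_rate = 0.1, min_length = 20),
  scoring = list(match = 2, mismatch = 6, gap_open = 5, gap_extend = 3),
  classify = list(matching_threshold = NULL, ambiguity_threshold = 2),
  count_cutoff = 0,
  normalization = "cpm",
  ranking = list(p0 = 0.05, n_permutations = 1000),
  clustering = list(n_top = 25, selection = "variance",
                    distance = "euclidean", linkage = "complete"),
  seed = 1
)

merge_defaults <- function(cfg, defaults) {
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) {
      cfg[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]]) && is.list(cfg[[k]])) {
      cfg[[k]] <- merge_defaults(cfg[[k]], defaults[[k]])
    }
  }
  cfg
}

#' Validate a run configuration
#'
#' Fills defaults and checks the whole configuration at once, so every
#' violation is reported together rather than one per run attempt.
#'
#' @param config a configuration list, or path to a YAML file with the
#'   same structure: `samples` (list of `sample_id`, `fastq`,
#'   `condition`, `control`), `library` (`path`, `adapter`),
#'   `screen_direction`, `trim`, `scoring`, `classify`, `count_cutoff`,
#'   `normalization`, `ranking`, `clustering`, `output_dir`, `seed`.
#' @return A validated `run_config` list with defaults filled; on
#'   invalid input, a character vector of all violations with class
#'   `config_errors`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- merge_defaults(config, config_defaults)
  errors <- character()

  if (is.null(cfg$samples) || length(cfg$samples) == 0) {
    errors <- c(errors, "no samples defined")
  } else {
    ids <- vapply(cfg$samples, function(s) s$sample_id %||% NA_character_,
                  "")
    if (anyNA(ids)) errors <- c(errors, "every sample needs a sample_id")
    if (anyDuplicated(ids)) errors <- c(errors, "sample_ids must be unique")
    ctrl <- vapply(cfg$samples, function(s) isTRUE(s$control), logical(1))
    if (!any(ctrl)) {
      errors <- c(errors, "at least one control sample is required")
    }
    missing_fq <- vapply(cfg$samples, function(s)
      is.null(s$fastq) || !file.exists(s$fastq), logical(1))
    if (any(missing_fq)) {
      errors <- c(errors, paste0("FASTQ not found for sample(s): ",
                                 paste(ids[missing_fq], collapse = ", ")))
    }
  }
  if (is.null(cfg$library$path) || !file.exists(cfg$library$path %||% "")) {
    errors <- c(errors, "library file missing or not found")
  }
  if (is.null(cfg$library$adapter)) {
    errors <- c(errors, "library adapter is required")
  }
  if (!cfg$screen_direction %in% c("enrichment", "depletion")) {
    errors <- c(errors, "screen_direction must be enrichment or depletion")
  }
  if (!cfg$normalization %in% c("cpm", "total", "size-factor")) {
    errors <- c(errors,
                "normalization must be one of cpm, total, size-factor")
  }
  if (is.null(cfg$output_dir)) errors <- c(errors, "output_dir is required")

  if (length(errors) > 0) {
    return(structure(errors, class = "config_errors"))
  }
  structure(cfg, class = "run_config")
}

#' Run the full screen analysis pipeline
#'
#' Executes trim, align, count, normalize, per-sample statistics,
#' enrichment/depletion testing, alpha-RRA gene ranking and sample
#' clustering in order, comparing every treatment sample against the
#' control set. With a single control sample only fold-changes are
#' reported (no p-values, no gene ranking). All tables are written under
#' `output_dir` together with a run manifest; read counts are conserved
#' and audited across stages (trim tallies sum to reads in, category
#' tallies to candidates extracted).
#'
#' @param config a `run_config` from [validate_config], a raw list, or a
#'   YAML path.
#' @return Invisibly, a list with the in-memory results: `trim_summary`,
#'   `alignment_summary`, `counts_raw`, `counts_norm`, `gene_counts`,
#'   `sample_stats`, `correlations`, `sgrna_results`, `gene_rankings`,
#'   `clustering`, `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  if (inherits(config, "config_errors")) {
    stop("invalid configuration:\n  - ",
         paste(config, collapse = "\n  - "))
  }
  cfg <- config
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  lib <- read_sgrna_library(cfg$library$path, cfg$library$adapter)
  index <- build_index(lib)
  scoring <- do.call(scoring_scheme, cfg$scoring)

  ids <- vapply(cfg$samples, `[[`, "", "sample_id")
  is_control <- vapply(cfg$samples, function(s) isTRUE(s$control),
                       logical(1))
  conditions <- vapply(cfg$samples, function(s)
    s$condition %||% s$sample_id, "")

  trims <- list(); aligns <- list(); counts <- list()
  for (k in seq_along(cfg$samples)) {
    s <- cfg$samples[[k]]
    reads <- read_fastq(s$fastq)
    trimmed <- trim_reads(reads, cfg$library$adapter,
                          cfg$trim$error_rate, cfg$trim$min_length)
    classified <- classify_reads(trimmed, index, scoring,
                                 cfg$classify$matching_threshold,
                                 cfg$classify$ambiguity_threshold)
    ts <- trim_summary(trimmed)
    as_ <- alignment_summary(classified)
    stopifnot(sum(ts[-1]) == nrow(reads),
              sum(as_) == ts$extracted)  # conservation audit
    trims[[s$sample_id]] <- ts
    aligns[[s$sample_id]] <- as_
    counts[[s$sample_id]] <- count_sample(classified, lib)
  }

  m_raw <- count_matrix(lib, counts) |>
    apply_count_cutoff(cfg$count_cutoff)
  m_norm <- normalize_counts(m_raw, cfg$normalization)
  g_norm <- gene_counts(m_norm)
  stats_tbl <- sample_stats(m_norm, g_norm)

  corr <- purrr::map_dfr(unique(conditions), function(cond) {
    cols <- ids[conditions == cond]
    if (length(cols) < 2) return(tibble::tibble())
    dplyr::mutate(replicate_correlation(m_norm, cols),
                  condition = cond, .before = 1)
  })

  controls <- ids[is_control]
  treatments <- ids[!is_control]
  direction <- cfg$screen_direction

  sgrna_results <- list(); gene_rankings <- list()
  model <- NULL
  if (length(controls) >= 2) {
    model <- estimate_dispersion(m_norm, controls)
    for (i in seq_along(treatments)) {
      trt <- treatments[i]
      res <- test_sample(m_norm, trt, model, direction)
      sgrna_results[[trt]] <- res
      gene_rankings[[trt]] <- arra_ranking(
        res, cfg$ranking$p0, cfg$ranking$n_permutations,
        seed = cfg$seed + i)
    }
  } else {
    for (trt in treatments) {
      sgrna_results[[trt]] <- fold_change_only(m_norm, trt, controls[1])
    }
  }

  clustering <- NULL
  if (length(ids) >= 2) {
    sel <- select_top_sgrnas(
      m_norm, min(cfg$clustering$n_top, nrow(m_norm)),
      cfg$clustering$selection)
    clustering <- cluster_samples(m_norm, sel, cfg$clustering$distance,
                                  cfg$clustering$linkage)
  }

  out <- list(
    trim_summary = dplyr::bind_rows(trims, .id = "sample_id"),
    alignment_summary = dplyr::bind_rows(aligns, .id = "sample_id"),
    counts_raw = m_raw, counts_norm = m_norm, gene_counts = g_norm,
    sample_stats = stats_tbl, correlations = corr,
    sgrna_results = sgrna_results, gene_rankings = gene_rankings,
    clustering = clustering, output_dir = cfg$output_dir
  )
  write_report(out, cfg, model)
  invisible(out)
}

write_report <- function(out, cfg, model) {
  d <- cfg$output_dir
  readr::write_tsv(out$trim_summary, file.path(d, "trim_summary.tsv"))
  readr::write_tsv(out$alignment_summary,
                   file.path(d, "alignment_summary.tsv"))
  write_counts(out$counts_raw, file.path(d, "counts_raw.tsv"))
  write_counts(out$counts_norm, file.path(d, "counts_normalized.tsv"))
  write_counts(out$gene_counts, file.path(d, "gene_counts.tsv"))
  readr::write_tsv(out$sample_stats, file.path(d, "sample_stats.tsv"))
  if (nrow(out$correlations) > 0) {
    readr::write_tsv(out$correlations,
                     file.path(d, "replicate_correlation.tsv"))
  }
  for (trt in names(out$sgrna_results)) {
    readr::write_tsv(out$sgrna_results[[trt]],
                     file.path(d, paste0("sgrna_results_", trt, ".tsv")))
  }
  for (trt in names(out$gene_rankings)) {
    readr::write_tsv(tibble::as_tibble(out$gene_rankings[[trt]]),
                     file.path(d, paste0("gene_ranking_", trt, ".tsv")))
  }
  if (!is.null(out$clustering)) {
    readr::write_tsv(out$clustering$merges,
                     file.path(d, "sample_clustering.tsv"))
  }
  manifest <- list(
    package = "poolscreen",
    version = as.character(utils::packageVersion("poolscreen")),
    seed = cfg$seed,
    normalization = cfg$normalization,
    screen_direction = cfg$screen_direction,
    n_samples = length(cfg$samples),
    fold_change_only = is.null(model),
    dispersion = if (!is.null(model)) model$D else NULL,
    config = cfg[setdiff(names(cfg), "samples")],
    samples = cfg$samples
  )
  jsonlite::write_json(manifest, file.path(d, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(d)
}
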