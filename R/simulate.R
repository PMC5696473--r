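random_kmers <- function(n, k) {
  matrix(sample(c("A", "C", "G", "T"), n * k, replace = TRUE), nrow = n) |>
    apply(1, paste0, collapse = "")
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  force(code)
}

#' Simulate an sgRNA library
#'
#' Random distinct 20-mers for `n_genes` genes with `sgrnas_per_gene`
#' guides each (six guides per gene being the usual genome-wide design).
#' `n_shared` extra sequence duplications can be injected — pairs of
#' entries in different genes carrying the same 20-mer — to exercise
#' ambiguity handling.
#'
#' @param n_genes number of genes.
#' @param sgrnas_per_gene guides per gene (default 6).
#' @param adapter 5' adapter of the simulated construct.
#' @param n_shared number of duplicated-sequence pairs (default 0).
#' @param seed RNG seed.
#' @return An [sgrna_library].
#' @export
simulate_library <- function(n_genes, sgrnas_per_gene = 6,
                             adapter = "TTGTGGAAAGGACGAAACACCG",
                             n_shared = 0, seed = NULL) {
  with_seed(seed, {
    n <- n_genes * sgrnas_per_gene
    seqs <- unique(random_kmers(ceiling(n * 1.2) + 10, 20))
    while (length(seqs) < n) {
      seqs <- unique(c(seqs, random_kmers(n, 20)))
    }
    seqs <- seqs[seq_len(n)]
    genes <- rep(sprintf("gene%03d", seq_len(n_genes)),
                 each = sgrnas_per_gene)
    ids <- paste0(genes, "_sg", rep(seq_len(sgrnas_per_gene), n_genes))
    if (n_shared > 0) {
      stopifnot(n_genes >= 2 * n_shared)
      # entry 1 of gene 2k gets the sequence of entry 1 of gene 2k-1
      for (k in seq_len(n_shared)) {
        src <- (2 * k - 2) * sgrnas_per_gene + 1
        dst <- (2 * k - 1) * sgrnas_per_gene + 1
        seqs[dst] <- seqs[src]
      }
    }
    sgrna_library(tibble::tibble(sgrna_id = ids, gene_id = genes,
                                 sequence = seqs), adapter)
  })
}

#' Simulate negative-binomial screen counts
#'
#' Control counts are drawn per sgRNA from NB with mean mu_i and
#' variance `mu_i + D mu_i^2` (Poisson when `dispersion = 0`), the NB
#' parameterized by size `1/D` exactly as in the testing module, so
#' generator and estimator share one convention. Per-sgRNA baseline
#' means are lognormal around `baseline_mean` to mimic uneven library
#' representation. Treatment samples use the same means except for
#' sgRNAs of spiked genes, whose means are multiplied by the spike
#' fold effect.
#'
#' @param lib an [sgrna_library].
#' @param baseline_mean mean control count per sgRNA (default 200).
#' @param dispersion NB dispersion D >= 0 (default 0.2).
#' @param n_controls,n_treatments replicate numbers (default 2 each).
#' @param spiked_genes tibble with `gene_id`, `fold` (empty for none).
#' @param mean_sdlog lognormal sdlog of per-sgRNA baselines
#'   (default 0.3; 0 gives identical means).
#' @param seed RNG seed.
#' @return List: `counts` (raw count matrix; controls named
#'   `control_1..`, treatments `treatment_1..`), `truth` (per-sgRNA true
#'   control/treatment means, spiked flag, `dispersion`).
#' @export
simulate_counts <- function(lib, baseline_mean = 200, dispersion = 0.2,
                            n_controls = 2, n_treatments = 2,
                            spiked_genes = NULL, mean_sdlog = 0.3,
                            seed = NULL) {
  stopifnot(inherits(lib, "sgrna_library"), dispersion >= 0)
  with_seed(seed, {
    n <- nrow(lib)
    mu <- if (mean_sdlog > 0) {
      stats::rlnorm(n, log(baseline_mean) - mean_sdlog^2 / 2, mean_sdlog)
    } else rep(baseline_mean, n)

    fold <- rep(1, n)
    if (!is.null(spiked_genes) && nrow(spiked_genes) > 0) {
      stopifnot(all(spiked_genes$gene_id %in% lib$gene_id))
      for (k in seq_len(nrow(spiked_genes))) {
        fold[lib$gene_id == spiked_genes$gene_id[k]] <- spiked_genes$fold[k]
      }
    }
    mu_trt <- mu * fold

    draw <- function(means) {
      if (dispersion == 0) rpois(n, means)
      else rnbinom(n, size = 1 / dispersion, mu = means)
    }
    cols <- c(
      setNames(lapply(seq_len(n_controls), function(i) draw(mu)),
               sprintf("control_%d", seq_len(n_controls))),
      setNames(lapply(seq_len(n_treatments), function(i) draw(mu_trt)),
               sprintf("treatment_%d", seq_len(n_treatments)))
    )
    counts <- count_matrix(lib, lapply(cols, function(x)
      tibble::tibble(sgrna_id = lib$sgrna_id, count = as.integer(x))))
    truth <- tibble::tibble(
      sgrna_id = lib$sgrna_id, gene_id = lib$gene_id,
      control_mean = mu, treatment_mean = mu_trt, spiked = fold != 1
    )
    list(counts = counts, truth = truth, dispersion = dispersion)
  })
}

#' Write a counts column as staggered FASTQ reads
#'
#' Emits `count[i]` reads per sgRNA i, each laid out as a random-length
#' stagger of random bases, the library adapter, the 20 nt protospacer
#' and a fixed 3' tail — the staggered amplicon layout that diversifies
#' per-cycle base composition on the sequencer. Optional per-base
#' substitution errors; read order is shuffled. Read ids encode the
#' source sgRNA, which serves as per-read ground truth.
#'
#' @param counts tibble `sgrna_id`, `count` (e.g. one sample column of a
#'   simulated matrix).
#' @param lib the [sgrna_library] (supplies sequences and adapter).
#' @param path output FASTQ path (`.gz` for compressed).
#' @param stagger_lengths candidate stagger lengths (default 0:7).
#' @param seq_error_rate per-base substitution probability (default 0).
#' @param tail fixed 3' tail sequence.
#' @param seed RNG seed.
#' @return `path`, invisibly.
#' @export
counts_to_fastq <- function(counts, lib, path, stagger_lengths = 0:7,
                            seq_error_rate = 0, tail = "GTTTTAGAGCTAGAA",
                            seed = NULL) {
  stopifnot(inherits(lib, "sgrna_library"), seq_error_rate >= 0,
            seq_error_rate < 0.2, all(stagger_lengths >= 0))
  adapter <- attr(lib, "adapter")
  with_seed(seed, {
    idx <- rep(match(counts$sgrna_id, lib$sgrna_id), counts$count)
    n <- length(idx)
    if (n == 0) {
      writeLines(character(), path)
      return(invisible(path))
    }
    stag_len <- sample(stagger_lengths, n, replace = TRUE)
    staggers <- vapply(stag_len, function(l)
      paste0(sample(c("A", "C", "G", "T"), l, replace = TRUE),
             collapse = ""), "")
    seqs <- paste0(staggers, adapter, lib$sequence[idx], tail)
    if (seq_error_rate > 0) {
      seqs <- add_substitutions(seqs, seq_error_rate)
    }
    ord <- sample.int(n)
    reads <- tibble::tibble(
      read_id = paste0("read", seq_len(n), ":", lib$sgrna_id[idx])[ord],
      sequence = seqs[ord]
    )
    write_fastq(reads, path)
  })
}

add_substitutions <- function(seqs, rate) {
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- which(stats::runif(length(flat)) < rate)
  if (length(hit) > 0) {
    bases <- c("A", "C", "G", "T")
    repl <- vapply(flat[hit], function(b)
      sample(setdiff(bases, b), 1), "", USE.NAMES = FALSE)
    flat[hit] <- repl
  }
  starts <- cumsum(c(1, lens[-length(lens)]))
  vapply(seq_along(seqs), function(i)
    paste0(flat[starts[i]:(starts[i] + lens[i] - 1)], collapse = ""), "")
}

#' Simulate a complete screen on disk
#'
#' Library TSV, per-sample staggered FASTQ files and a ground-truth JSON
#' under `dir`, ready for [run_pipeline].
#'
#' @inheritParams simulate_counts
#' @inheritParams counts_to_fastq
#' @param dir output directory (created).
#' @param n_genes,sgrnas_per_gene library size.
#' @param adapter construct adapter.
#' @return List with `library`, `counts`, `truth`, `config` (a ready run
#'   configuration list), invisibly.
#' @export
simulate_screen <- function(dir, n_genes = 100, sgrnas_per_gene = 6,
                            adapter = "TTGTGGAAAGGACGAAACACCG",
                            baseline_mean = 200, dispersion = 0.2,
                            n_controls = 2, n_treatments = 2,
                            spiked_genes = NULL, stagger_lengths = 0:7,
                            seq_error_rate = 0, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lib <- simulate_library(n_genes, sgrnas_per_gene, adapter, seed = seed)
  sim <- simulate_counts(lib, baseline_mean, dispersion, n_controls,
                         n_treatments, spiked_genes, seed = seed + 1)
  lib_path <- file.path(dir, "library.tsv")
  write_sgrna_library(lib, lib_path)

  samples <- sample_cols(sim$counts)
  fastqs <- file.path(dir, paste0(samples, ".fastq.gz"))
  for (k in seq_along(samples)) {
    counts_to_fastq(
      tibble::tibble(sgrna_id = sim$counts$sgrna_id,
                     count = sim$counts[[samples[k]]]),
      lib, fastqs[k], stagger_lengths, seq_error_rate, seed = seed + 1 + k)
  }
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"))

  config <- list(
    samples = purrr::map2(samples, fastqs, function(s, f) list(
      sample_id = s, fastq = f,
      condition = sub("_[0-9]+$", "", s),
      control = grepl("^control", s)
    )),
    library = list(path = lib_path, adapter = adapter),
    screen_direction = "enrichment",
    output_dir = file.path(dir, "results"),
    seed = seed
  )
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  invisible(list(library = lib, counts = sim$counts, truth = sim$truth,
                 config = config))
}
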