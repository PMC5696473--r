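sample_cols <- function(m) setdiff(names(m), c("sgrna_id", "gene_id"))

count_normalization <- function(m) attr(m, "normalization") %||% "raw"

`%||%` <- function(a, b) if (is.null(a)) b else a

set_normalization <- function(m, method) {
  attr(m, "normalization") <- method
  m
}

#' Count kept reads per sgRNA
#'
#' Only unique and tolerated reads carry an assignment and are counted;
#' ambiguous and failed reads are discarded. Every library sgRNA appears
#' in the result, zero-filled.
#'
#' @param classified output of [classify_reads].
#' @param lib an [sgrna_library].
#' @return Tibble `sgrna_id`, `count`, in library order; the counts sum
#'   to the number of unique + tolerated reads.
#' @export
count_sample <- function(classified, lib) {
  stopifnot(inherits(lib, "sgrna_library"))
  assigned <- classified$assigned_sgrna[!is.na(classified$assigned_sgrna)]
  unknown <- setdiff(unique(assigned), lib$sgrna_id)
  if (length(unknown) > 0) {
    stop("reads assigned to sgRNAs absent from the library: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }
  tab <- table(factor(assigned, levels = lib$sgrna_id))
  tibble::tibble(sgrna_id = lib$sgrna_id, count = as.integer(tab))
}

#' Assemble a count matrix across samples
#'
#' @param lib an [sgrna_library].
#' @param sample_counts named list of per-sample count tibbles from
#'   [count_sample] (names become sample columns).
#' @return A raw count matrix: tibble with `sgrna_id`, `gene_id` and one
#'   integer column per sample; normalization recorded as attribute
#'   `normalization = "raw"`.
#' @export
count_matrix <- function(lib, sample_counts) {
  stopifnot(inherits(lib, "sgrna_library"), length(sample_counts) > 0,
            !is.null(names(sample_counts)))
  m <- tibble::tibble(sgrna_id = lib$sgrna_id, gene_id = lib$gene_id)
  for (s in names(sample_counts)) {
    sc <- sample_counts[[s]]
    stopifnot(identical(sc$sgrna_id, lib$sgrna_id))
    m[[s]] <- sc$count
  }
  set_normalization(m, "raw")
}

#' Aggregate sgRNA counts to gene level
#'
#' Gene counts sum the counts of every sgRNA targeting the gene; column
#' totals are preserved.
#'
#' @param m a count matrix (raw or normalized).
#' @return Tibble `gene_id` plus the sample columns, same normalization
#'   attribute.
#' @export
gene_counts <- function(m) {
  out <- m |>
    dplyr::select(-"sgrna_id") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), sum), .groups = "drop")
  set_normalization(out, count_normalization(m))
}

#' Zero out low counts by a cpm cutoff
#'
#' Noise removal: raw counts whose cpm equivalent
#' (`count / column_total * 1e6`) falls below `cutoff` are set to 0;
#' everything else keeps its raw value. Applied before normalization so
#' the cutoff is independent of the normalization method. A cutoff of 0
#' is the identity; all-zero columns pass through unchanged.
#'
#' @param m raw count matrix.
#' @param cutoff cpm threshold (default 0).
#' @return Raw count matrix with small counts zeroed.
#' @export
apply_count_cutoff <- function(m, cutoff = 0) {
  stopifnot(count_normalization(m) == "raw", cutoff >= 0)
  if (cutoff == 0) return(m)
  for (s in sample_cols(m)) {
    tot <- sum(m[[s]])
    if (tot > 0) {
      m[[s]][m[[s]] / tot * 1e6 < cutoff] <- 0L
    }
  }
  m
}

#' Normalize a count matrix
#'
#' Methods: `cpm` divides by the column total and multiplies by 1e6;
#' `total` divides by the column total and multiplies by the mean column
#' total across samples; `size-factor` divides each column by the median
#' ratio of its counts to the per-sgRNA geometric means, the geometric
#' means being taken over sgRNAs with strictly positive counts in every
#' sample (the median-ratio method).
#'
#' @param m raw count matrix.
#' @param method one of `"cpm"`, `"total"`, `"size-factor"`.
#' @return Normalized count matrix (attribute `normalization` set).
#' @export
normalize_counts <- function(m, method = c("cpm", "total", "size-factor")) {
  method <- match.arg(method)
  stopifnot(count_normalization(m) == "raw")
  samples <- sample_cols(m)
  vals <- as.matrix(m[samples])
  totals <- colSums(vals)

  norm <- switch(method,
    "cpm" = sweep(vals, 2, ifelse(totals > 0, totals, 1), "/") * 1e6,
    "total" = sweep(vals, 2, ifelse(totals > 0, totals, 1), "/") *
      mean(totals),
    "size-factor" = {
      all_pos <- rowSums(vals > 0) == ncol(vals)
      if (!any(all_pos)) {
        stop("size-factor normalization needs at least one sgRNA with ",
             "nonzero counts in every sample; use cpm or total instead")
      }
      geo <- exp(rowMeans(log(vals[all_pos, , drop = FALSE])))
      s <- apply(vals[all_pos, , drop = FALSE], 2,
                 function(col) median(col / geo))
      sweep(vals, 2, s, "/")
    })

  out <- m
  out[samples] <- tibble::as_tibble(norm)
  set_normalization(out, method)
}

#' Gini coefficient of a count vector
#'
#' Inequality of the read-count distribution; 0 for a perfectly uniform
#' library, approaching 1 when a few sgRNAs dominate. Computed by the
#' sorted-rank identity `G = 2 * sum(i * x_(i)) / (n * sum(x)) -
#' (n + 1) / n`; an all-zero vector yields 0 by convention.
#'
#' @param x non-negative numeric vector.
#' @return Gini coefficient in \[0, 1\].
#' @export
gini <- function(x) {
  stopifnot(all(x >= 0))
  n <- length(x)
  if (n == 0 || sum(x) == 0) return(0)
  xs <- sort(x)
  2 * sum(seq_len(n) * xs) / (n * sum(xs)) - (n + 1) / n
}

#' Per-sample count-distribution statistics
#'
#' Median, population standard deviation, extremes, sgRNA and gene
#' representation (fraction with count > 0), and the Gini coefficient of
#' the sgRNA-level counts.
#'
#' @param m normalized (or raw) sgRNA count matrix.
#' @param gene_m matching gene-level matrix (from [gene_counts]);
#'   computed from `m` when omitted.
#' @return Tibble with one row per sample.
#' @export
sample_stats <- function(m, gene_m = gene_counts(m)) {
  samples <- sample_cols(m)
  stopifnot(identical(samples, sample_cols(gene_m)))
  purrr::map_dfr(samples, function(s) {
    x <- m[[s]]
    g <- gene_m[[s]]
    tibble::tibble(
      sample_id = s,
      median = median(x),
      stdev = sqrt(mean((x - mean(x))^2)),
      maximum = max(x),
      minimum = min(x),
      sgrna_representation = mean(x > 0),
      gene_representation = mean(g > 0),
      gini = gini(x)
    )
  })
}

#' Write a count matrix to TSV
#'
#' @param m count matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path) {
  readr::write_tsv(tibble::as_tibble(m), path)
  invisible(path)
}
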