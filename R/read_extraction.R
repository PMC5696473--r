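#' Read a FASTQ file into a tibble
#'
#' Plain or gzip-compressed FASTQ (compression detected from the file
#' magic by the reader). Qualities are carried along but never used for
#' trimming decisions, which are sequence-only.
#'
#' @param path FASTQ or FASTQ.gz file.
#' @return Tibble with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readr::read_lines(path)
  if (length(lines) %% 4 != 0) {
    stop("truncated FASTQ: ", path, " ends mid-record after record ",
         length(lines) %/% 4)
  }
  if (length(lines) == 0) {
    return(tibble::tibble(read_id = character(), sequence = character(),
                          quality = character()))
  }
  idx <- seq(1, length(lines), by = 4)
  headers <- lines[idx]
  if (any(substr(headers, 1, 1) != "@")) {
    stop("malformed FASTQ header at record ",
         which(substr(headers, 1, 1) != "@")[[1]])
  }
  tibble::tibble(
    read_id = sub("^@", "", sub("\\s.*$", "", headers)),
    sequence = toupper(lines[idx + 1]),
    quality = lines[idx + 3]
  )
}

#' Write reads to FASTQ
#'
#' @param reads tibble with `read_id`, `sequence` and optionally
#'   `quality` (defaults to "I" per base).
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("quality" %in% names(reads)) reads$quality else
    strrep("I", nchar(reads$sequence))
  txt <- paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", qual)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(txt, con)
  invisible(path)
}

#' Locate the 5' adapter in reads
#'
#' Finds the best occurrence of the full adapter inside each read by
#' semi-global alignment: the adapter is entirely consumed while the read
#' flanks are free, and substitutions and indels each cost one error.
#' An occurrence is accepted when its error count is at most
#' `floor(error_rate * nchar(adapter))`; ties are broken by fewest
#' errors, then leftmost start. This tolerates both the variable-length
#' staggers of pooled amplicon layouts and indels upstream of the
#' protospacer. The adapter may not overhang the read's 5' end.
#'
#' @param reads character vector of read sequences, or a tibble with a
#'   `sequence` column.
#' @param adapter adapter sequence (>= 10 nt).
#' @param error_rate tolerated error fraction of the adapter length
#'   (default 0.1).
#' @return Tibble with columns `start`, `end` (0-based, end exclusive)
#'   and `n_errors`; all NA where no occurrence fits the budget.
#' @export
locate_adapter <- function(reads, adapter, error_rate = 0.1) {
  if (is.data.frame(reads)) reads <- reads$sequence
  adapter <- validate_adapter(adapter)
  stopifnot(error_rate >= 0, error_rate < 0.5)
  max_err <- floor(error_rate * nchar(adapter))
  m <- cpp_locate_adapter(toupper(reads), adapter, max_err)
  tibble::as_tibble(m)
}

#' Trim reads to their 20 nt sgRNA candidate
#'
#' Locates the adapter with [locate_adapter] and takes the first 20 bases
#' after it. Reads keep their candidate only when at least `min_length`
#' bases remain past the adapter; shorter remainders are flagged
#' `too_short` and reads without an adapter occurrence
#' `adapter_not_found`. The candidate never contains adapter bases.
#'
#' @inheritParams locate_adapter
#' @param reads tibble with `read_id` and `sequence` (e.g. from
#'   [read_fastq]).
#' @param min_length minimum remainder length after the adapter
#'   (default 20).
#' @return Tibble with `read_id`, `status` (one of `extracted`,
#'   `adapter_not_found`, `too_short`), `candidate` (20-mer, NA unless
#'   extracted) and `adapter_end`.
#' @export
trim_reads <- function(reads, adapter, error_rate = 0.1, min_length = 20) {
  stopifnot(is.data.frame(reads), min_length >= 1)
  hits <- locate_adapter(reads$sequence, adapter, error_rate)
  remainder <- nchar(reads$sequence) - hits$end
  status <- dplyr::case_when(
    is.na(hits$end) ~ "adapter_not_found",
    remainder < min_length ~ "too_short",
    TRUE ~ "extracted"
  )
  candidate <- ifelse(status == "extracted",
                      substr(reads$sequence, hits$end + 1, hits$end + 20),
                      NA_character_)
  tibble::tibble(
    read_id = reads$read_id,
    status = status,
    candidate = candidate,
    adapter_end = hits$end
  )
}

#' Summarise a trim run
#'
#' @param trimmed output of [trim_reads].
#' @return One-row tibble: `reads_total`, `extracted`,
#'   `adapter_not_found`, `too_short`.
#' @export
trim_summary <- function(trimmed) {
  tibble::tibble(
    reads_total = nrow(trimmed),
    extracted = sum(trimmed$status == "extracted"),
    adapter_not_found = sum(trimmed$status == "adapter_not_found"),
    too_short = sum(trimmed$status == "too_short")
  )
}
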