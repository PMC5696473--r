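#' Construct and validate an sgRNA library
#'
#' An sgRNA library is a tibble with columns `sgrna_id`, `gene_id` and
#' `sequence` (a 20 nt protospacer over A/C/G/T), carrying the 5' adapter
#' of the sequencing construct as an attribute. The adapter is the fixed
#' vector-derived sequence immediately upstream of the sgRNA in every
#' read; locating it is what anchors read extraction.
#'
#' @param entries data frame with columns `sgrna_id`, `gene_id`,
#'   `sequence`.
#' @param adapter 5' adapter sequence (A/C/G/T, length >= 10).
#' @return A tibble of class `sgrna_library` with the adapter attached as
#'   attribute `adapter`.
#' @export
sgrna_library <- function(entries, adapter) {
  stopifnot(is.data.frame(entries))
  required <- c("sgrna_id", "gene_id", "sequence")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0) {
    stop("library is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  lib <- tibble::as_tibble(entries[required])
  lib$sgrna_id <- as.character(lib$sgrna_id)
  lib$gene_id <- as.character(lib$gene_id)
  lib$sequence <- toupper(as.character(lib$sequence))

  bad_len <- nchar(lib$sequence) != 20L
  bad_chr <- grepl("[^ACGT]", lib$sequence)
  if (any(bad_len | bad_chr)) {
    offenders <- lib$sgrna_id[bad_len | bad_chr]
    stop("invalid sgRNA sequence (must be 20 nt over A/C/G/T) for: ",
         paste(utils::head(offenders, 5), collapse = ", "))
  }
  dup <- lib$sgrna_id[duplicated(lib$sgrna_id)]
  if (length(dup) > 0) {
    stop("duplicate sgrna_id: ", paste(unique(dup), collapse = ", "))
  }

  adapter <- validate_adapter(adapter)
  structure(lib, adapter = adapter,
            class = c("sgrna_library", class(lib)))
}

validate_adapter <- function(adapter) {
  stopifnot(is.character(adapter), length(adapter) == 1)
  adapter <- toupper(adapter)
  if (nchar(adapter) < 10 || grepl("[^ACGT]", adapter)) {
    stop("adapter must be >= 10 nt over A/C/G/T")
  }
  adapter
}

#' Read an sgRNA library file
#'
#' Accepts comma- or tab-delimited files (sniffed from the first line)
#' with fixed column order (sgrna_id, gene_id, sequence). A header row is
#' auto-detected: a first row whose third field is not a valid 20-mer
#' over A/C/G/T is treated as a header and skipped.
#'
#' @param path path to the CSV/TSV library file.
#' @inheritParams sgrna_library
#' @return An [sgrna_library] tibble.
#' @export
read_sgrna_library <- function(path, adapter) {
  if (!file.exists(path)) stop("library file not found: ", path)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("library file is empty: ", path)
  delim <- if (grepl("\t", lines[[1]])) "\t" else ","

  fields <- strsplit(lines, delim, fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields < 3)
  if (length(bad) > 0) {
    stop("malformed library row (expected >= 3 fields) at line ", bad[[1]])
  }
  first_seq <- toupper(trimws(fields[[1]][[3]]))
  has_header <- !(nchar(first_seq) == 20 && !grepl("[^ACGT]", first_seq))
  if (has_header) fields <- fields[-1]
  if (length(fields) == 0) stop("library file has a header but no rows: ", path)

  entries <- tibble::tibble(
    sgrna_id = trimws(vapply(fields, `[[`, "", 1L)),
    gene_id  = trimws(vapply(fields, `[[`, "", 2L)),
    sequence = trimws(vapply(fields, `[[`, "", 3L))
  )
  sgrna_library(entries, adapter)
}

#' Write a library back to TSV
#'
#' @param lib an [sgrna_library].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sgrna_library <- function(lib, path) {
  stopifnot(inherits(lib, "sgrna_library"))
  readr::write_tsv(tibble::as_tibble(lib)[c("sgrna_id", "gene_id", "sequence")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Find sequences shared by multiple library entries
#'
#' Identical protospacers carried by several entries make reads
#' unassignable: any read matching them aligns equally well to every
#' carrier and is discarded as ambiguous under the default thresholds.
#' Genome-wide libraries can carry thousands of such repeats.
#'
#' @param lib an [sgrna_library].
#' @return A tibble with one row per shared sequence: `sequence`,
#'   `n_sgrnas`, and a list-column `sgrna_ids` of the carriers; zero rows
#'   when all sequences are distinct.
#' @export
find_shared_sequences <- function(lib) {
  stopifnot(inherits(lib, "sgrna_library"))
  tibble::as_tibble(lib) |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(n_sgrnas = dplyr::n(),
                     sgrna_ids = list(.data$sgrna_id),
                     .groups = "drop") |>
    dplyr::filter(.data$n_sgrnas >= 2) |>
    dplyr::arrange(.data$sequence)
}

#' Gene index of a library
#'
#' @param lib an [sgrna_library].
#' @return Named list mapping each `gene_id` to its `sgrna_id`s.
#' @export
gene_index <- function(lib) {
  stopifnot(inherits(lib, "sgrna_library"))
  split(lib$sgrna_id, lib$gene_id)
}

#' Built-in 5' adapter presets
#'
#' Screens run with a published library reuse its cloning vector, so the
#' 5' adapter is a property of the library. This table ships a small set
#' of common single-vector designs and is meant to be extended by
#' deployments; the adapter can always be given explicitly instead.
#'
#' @return A tibble with columns `library_name` and `adapter`.
#' @export
adapter_presets <- function() {
  tibble::tribble(
    ~library_name, ~adapter,
    "lentiCRISPRv2", "TTGTGGAAAGGACGAAACACCG",
    "lentiGuide",    "TTGTGGAAAGGACGAAACACCG",
    "pLCKO",         "TGTGGAAAGGACGAAACACCG"
  )
}

#' @export
print.sgrna_library <- function(x, ...) {
  cat("sgRNA library: ", nrow(x), " sgRNAs, ",
      dplyr::n_distinct(x$gene_id), " genes; adapter ",
      attr(x, "adapter"), "\n", sep = "")
  NextMethod()
}
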