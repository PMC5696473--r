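#' Local alignment scoring scheme
#'
#' Defaults follow the common local-mode short-read scoring (match +2,
#' mismatch -6, gap open -5, gap extension -3), so a perfectly matching
#' 20-mer scores exactly 40 — the default matching threshold. A gap of
#' length k costs `gap_open + k * gap_extend`.
#'
#' @param match match bonus (positive).
#' @param mismatch mismatch penalty (positive; subtracted).
#' @param gap_open gap opening penalty (positive).
#' @param gap_extend per-base gap extension penalty (positive).
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2, mismatch = 6, gap_open = 5,
                           gap_extend = 3) {
  stopifnot(match > 0, mismatch > 0, gap_open > 0, gap_extend > 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Smith-Waterman local alignment score of sequence pairs
#'
#' Best local alignment score between `a[i]` and `b[i]` under the given
#' scoring scheme; a gap of length k costs `gap_open + k * gap_extend`,
#' and `N` never matches. This is the scorer behind [align_candidates].
#'
#' @param a,b character vectors of equal length (recycled if scalar).
#' @param scoring a [scoring_scheme].
#' @return Integer vector of local alignment scores (>= 0).
#' @export
sw_score <- function(a, b, scoring = scoring_scheme()) {
  n <- max(length(a), length(b))
  cpp_sw_scores(rep_len(toupper(a), n), rep_len(toupper(b), n),
                scoring$match, scoring$mismatch, scoring$gap_open,
                scoring$gap_extend)
}

#' Build an alignment index over a library
#'
#' The index couples an exact 20-mer lookup with a k-mer seed table:
#' every overlapping seed (default 8-mers, 13 per entry) maps to the
#' entries containing it, so inexact search only scores entries sharing
#' at least one seed with the candidate.
#'
#' @param lib an [sgrna_library].
#' @param seed_size seed k-mer length (default 8).
#' @return A list of class `sgrna_index`.
#' @export
build_index <- function(lib, seed_size = 8) {
  stopifnot(inherits(lib, "sgrna_library"), seed_size >= 4, seed_size <= 20)
  seqs <- lib$sequence
  ids <- lib$sgrna_id

  exact <- new.env(parent = emptyenv(), size = length(seqs) * 2L)
  for (i in seq_along(seqs)) {
    exact[[seqs[i]]] <- c(exact[[seqs[i]]], i)
  }

  n_seeds <- 20L - seed_size + 1L
  starts <- seq_len(n_seeds)
  seeds <- new.env(parent = emptyenv(), size = length(seqs) * n_seeds)
  for (i in seq_along(seqs)) {
    for (km in unique(substring(seqs[i], starts, starts + seed_size - 1L))) {
      seeds[[km]] <- c(seeds[[km]], i)
    }
  }

  structure(list(sequences = seqs, sgrna_ids = ids, exact = exact,
                 seeds = seeds, seed_size = seed_size),
            class = "sgrna_index")
}

#' Align 20 nt candidates against an indexed library
#'
#' Each candidate is Smith-Waterman scored against every library entry
#' sharing a seed k-mer with it. The best score is the primary alignment
#' and its entry the primary target (ties resolved to the
#' lexicographically smallest sgrna_id); the best score against any other
#' entry is the secondary alignment, reported only when it reaches a
#' floor of two matched bases (`2 * match`). Candidates hitting no seed
#' have no alignment.
#'
#' @param candidates character vector of 20-mers (duplicates fine; NAs
#'   propagate).
#' @param index an [build_index] result.
#' @param scoring a [scoring_scheme].
#' @return Tibble with one row per input candidate: `candidate`,
#'   `primary_score`, `primary_target`, `secondary_score`,
#'   `n_best_targets`.
#' @export
align_candidates <- function(candidates, index, scoring = scoring_scheme()) {
  stopifnot(inherits(index, "sgrna_index"), inherits(scoring, "scoring_scheme"))
  uniq <- unique(candidates[!is.na(candidates)])
  k <- index$seed_size
  starts <- seq_len(20L - k + 1L)
  floor_secondary <- 2L * scoring$match

  one <- function(cand) {
    hit_idx <- unique(unlist(
      lapply(unique(substring(cand, starts, starts + k - 1L)),
             function(s) index$seeds[[s]]),
      use.names = FALSE))
    if (is.null(hit_idx) || length(hit_idx) == 0) {
      return(list(NA_integer_, NA_character_, NA_integer_, NA_integer_))
    }
    sc <- cpp_sw_score_many(cand, index$sequences[hit_idx], scoring$match,
                            scoring$mismatch, scoring$gap_open,
                            scoring$gap_extend)
    best <- max(sc)
    best_at <- hit_idx[sc == best]
    primary <- sort(index$sgrna_ids[best_at])[[1]]
    n_best <- length(best_at)
    secondary <- if (n_best >= 2) best else {
      others <- sc[hit_idx != best_at]
      if (length(others) > 0 && max(others) >= floor_secondary)
        max(others) else NA_integer_
    }
    list(best, primary, as.integer(secondary), n_best)
  }

  res <- lapply(uniq, one)
  per_uniq <- tibble::tibble(
    candidate = uniq,
    primary_score = vapply(res, function(x) x[[1]], integer(1)),
    primary_target = vapply(res, function(x) x[[2]], character(1)),
    secondary_score = vapply(res, function(x) x[[3]], integer(1)),
    n_best_targets = vapply(res, function(x) x[[4]], integer(1))
  )
  dplyr::left_join(tibble::tibble(candidate = candidates), per_uniq,
                   by = "candidate")
}

#' Classify alignment scores
#'
#' A read fails when it has no alignment or its primary score is below
#' the matching threshold. Otherwise it is ambiguous when a secondary
#' score exists and the primary-secondary gap is below the ambiguity
#' threshold, tolerated when a secondary score exists with a gap at or
#' above it, and unique when no secondary score was reported.
#'
#' @param primary_score,secondary_score integer vectors (NA = absent).
#' @param matching_threshold minimum primary score to keep a read;
#'   default is the perfect-match score `20 * match` of `scoring`.
#' @param ambiguity_threshold minimum primary-secondary gap (default 2).
#' @param scoring [scoring_scheme] used to derive the default matching
#'   threshold.
#' @return Character vector over {unique, tolerated, ambiguous, failed}.
#' @export
classify_alignment <- function(primary_score, secondary_score,
                               matching_threshold = NULL,
                               ambiguity_threshold = 2,
                               scoring = scoring_scheme()) {
  if (is.null(matching_threshold)) matching_threshold <- 20L * scoring$match
  stopifnot(matching_threshold >= 0, ambiguity_threshold >= 0)
  dplyr::case_when(
    is.na(primary_score) | primary_score < matching_threshold ~ "failed",
    !is.na(secondary_score) &
      (primary_score - secondary_score) < ambiguity_threshold ~ "ambiguous",
    !is.na(secondary_score) ~ "tolerated",
    TRUE ~ "unique"
  )
}

#' Align and classify a sample of trimmed reads
#'
#' Takes the extracted candidates of a trim run through alignment and
#' classification. Only unique and tolerated reads receive an assigned
#' sgRNA; ambiguous and failed reads are kept in the table but carry no
#' assignment and are dropped at the counting stage. When several
#' entries tie for the primary score and the ambiguity threshold is 0,
#' assignment goes deterministically to the lexicographically smallest
#' sgrna_id.
#'
#' @param trimmed tibble from [trim_reads] (rows with status other than
#'   `extracted` are ignored).
#' @param index an [build_index] result.
#' @param scoring a [scoring_scheme].
#' @inheritParams classify_alignment
#' @return Tibble: `read_id`, `candidate`, `primary_score`,
#'   `secondary_score`, `n_best_targets`, `category`, `assigned_sgrna`.
#' @export
classify_reads <- function(trimmed, index, scoring = scoring_scheme(),
                           matching_threshold = NULL,
                           ambiguity_threshold = 2) {
  kept <- dplyr::filter(trimmed, .data$status == "extracted")
  aln <- align_candidates(kept$candidate, index, scoring)
  category <- classify_alignment(aln$primary_score, aln$secondary_score,
                                 matching_threshold, ambiguity_threshold,
                                 scoring)
  tibble::tibble(
    read_id = kept$read_id,
    candidate = kept$candidate,
    primary_score = aln$primary_score,
    secondary_score = aln$secondary_score,
    n_best_targets = aln$n_best_targets,
    category = category,
    assigned_sgrna = ifelse(category %in% c("unique", "tolerated"),
                            aln$primary_target, NA_character_)
  )
}

#' Tally alignment categories
#'
#' @param classified output of [classify_reads].
#' @return One-row tibble `n_unique`, `n_tolerated`, `n_ambiguous`,
#'   `n_failed`; the four tallies sum to the number of classified reads.
#' @export
alignment_summary <- function(classified) {
  tibble::tibble(
    n_unique = sum(classified$category == "unique"),
    n_tolerated = sum(classified$category == "tolerated"),
    n_ambiguous = sum(classified$category == "ambiguous"),
    n_failed = sum(classified$category == "failed")
  )
}
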