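make_lib <- function(seqs, genes = NULL) {
  n <- length(seqs)
  sgrna_library(tibble::tibble(
    sgrna_id = sprintf("sg%02d", seq_len(n)),
    gene_id = genes %||% sprintf("g%02d", seq_len(n)),
    sequence = seqs
  ), adapter = "TTGTGGAAAGGACGAAACACCG")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("index lookup covers the library, duplicates included", {
  set.seed(5)
  seqs <- c(replicate(3, random_seq(20)))
  lib <- make_lib(c(seqs, seqs[1]))  # sg04 duplicates sg01's sequence
  idx <- build_index(lib)
  expect_length(idx$sequences, 4)
  expect_equal(idx$exact[[seqs[1]]], c(1L, 4L))
  expect_equal(idx$exact[[seqs[2]]], 2L)
})

test_that("perfect matches score 40 with no secondary among distant entries", {
  # hand-built entries pairwise >= 8 mismatches apart and seed-disjoint
  seqs <- c("AAAAAAAAAACCCCCCCCCC",
            "GGGGGGGGGGTTTTTTTTTT",
            "ACACACACACGTGTGTGTGT")
  lib <- make_lib(seqs)
  aln <- align_candidates(seqs[1], build_index(lib))
  expect_equal(aln$primary_score, 40L)
  expect_equal(aln$primary_target, "sg01")
  expect_true(is.na(aln$secondary_score))
  expect_equal(aln$n_best_targets, 1L)
})

test_that("duplicated reference sequences tie primary and secondary", {
  set.seed(6)
  s <- random_seq(20)
  lib <- make_lib(c(s, s, random_seq(20)))
  aln <- align_candidates(s, build_index(lib))
  expect_equal(aln$primary_score, 40L)
  expect_equal(aln$secondary_score, 40L)
  expect_equal(aln$n_best_targets, 2L)
})

test_that("a single substitution scores 19 matches minus one mismatch", {
  set.seed(8)
  s <- random_seq(20)
  cand <- mutate_seq(s, 10)
  lib <- make_lib(c(s, "AAAAAAAAAACCCCCCCCCC"))
  aln <- align_candidates(cand, build_index(lib))
  expect_equal(aln$primary_score, 32L)  # 19*2 - 6
  expect_equal(aln$primary_target, "sg01")
})

shares_seed <- function(a, b, k = 8) {
  starts <- seq_len(20 - k + 1)
  length(intersect(substring(a, starts, starts + k - 1),
                   substring(b, starts, starts + k - 1))) > 0
}

test_that("pairwise scores equal the brute-force DP oracle", {
  set.seed(98)
  for (i in 1:60) {
    base <- random_seq(20)
    other <- switch(sample(4, 1),
      base,
      mutate_seq(base, sample(20, sample(1:5, 1))),
      # indel-shifted copy to exercise the affine gap states
      paste0(substr(base, 1, 9), substr(base, 11, 20), random_seq(1)),
      random_seq(20))
    expect_equal(sw_score(base, other), sw_oracle(base, other),
                 info = paste("pair", i))
  }
  # perfect self-alignment under defaults
  s <- random_seq(20)
  expect_equal(sw_score(s, s), 40L)
  # custom scoring changes the perfect score accordingly
  expect_equal(sw_score(s, s, scoring_scheme(match = 3)), 60L)
})

test_that("library-wide primary scores match the oracle on seeded entries", {
  set.seed(99)
  for (case in 1:20) {
    lib <- random_library(sample(5:25, 1), 2)
    idx <- build_index(lib)
    base <- sample(lib$sequence, 1)
    cand <- switch(1 + case %% 3,
      base,
      mutate_seq(base, sample(20, sample(1:3, 1))),
      random_seq(20))
    aln <- align_candidates(cand, idx)
    oracle_scores <- vapply(lib$sequence, function(ref)
      sw_oracle(cand, ref), numeric(1))
    oracle_best <- max(oracle_scores)
    best_seeded <- any(vapply(
      lib$sequence[oracle_scores == oracle_best],
      function(ref) shares_seed(cand, ref), logical(1)))
    if (best_seeded) {
      # the seed prefilter saw the best entry: scores must agree exactly
      expect_equal(aln$primary_score, oracle_best)
      expect_equal(
        unname(oracle_scores[which(lib$sgrna_id == aln$primary_target)]),
        oracle_best)
    } else {
      # prefilter can only drop sub-perfect entries, so default-threshold
      # classification is unaffected
      expect_lt(oracle_best, 40)
      expect_true(is.na(aln$primary_score) ||
                    aln$primary_score <= oracle_best)
    }
  }
})

test_that("classification follows the threshold scheme", {
  expect_equal(classify_alignment(40L, NA_integer_), "unique")
  expect_equal(classify_alignment(40L, 40L), "ambiguous")
  expect_equal(classify_alignment(40L, 39L), "ambiguous")
  expect_equal(classify_alignment(40L, 38L), "tolerated")
  expect_equal(classify_alignment(40L, 36L), "tolerated")
  expect_equal(classify_alignment(38L, NA_integer_), "failed")
  expect_equal(classify_alignment(NA_integer_, NA_integer_), "failed")
  # lowering the matching threshold rescues near-matches
  expect_equal(classify_alignment(38L, NA_integer_,
                                  matching_threshold = 32), "unique")
  # ambiguity threshold 0 never yields ambiguous
  expect_equal(classify_alignment(40L, 40L, ambiguity_threshold = 0),
               "tolerated")
})

test_that("category tallies conserve reads and respect thresholds", {
  set.seed(12)
  lib <- random_library(10, 2)
  idx <- build_index(lib)
  picks <- sample(nrow(lib), 30, replace = TRUE)
  trimmed <- tibble::tibble(
    read_id = paste0("r", 1:30),
    status = "extracted",
    candidate = lib$sequence[picks],
    adapter_end = 22L
  )
  cl <- classify_reads(trimmed, idx)
  sm <- alignment_summary(cl)
  expect_equal(sum(sm), 30L)
  expect_true(all(cl$category %in%
                    c("unique", "tolerated", "ambiguous", "failed")))
  expect_true(all(is.na(cl$assigned_sgrna) ==
                    (cl$category %in% c("ambiguous", "failed"))))
  # exact matches of distinct sequences all map back to their source
  kept <- !is.na(cl$assigned_sgrna)
  expect_equal(cl$assigned_sgrna[kept], lib$sgrna_id[picks][kept])

  # raising the matching threshold never gains kept reads
  cl_hi <- classify_reads(trimmed, idx, matching_threshold = 41)
  expect_lte(sum(cl_hi$category %in% c("unique", "tolerated")),
             sum(cl$category %in% c("unique", "tolerated")))
  # raising the ambiguity threshold never loses ambiguous reads
  cl_amb <- classify_reads(trimmed, idx, ambiguity_threshold = 10)
  expect_gte(sum(cl_amb$category == "ambiguous"),
             sum(cl$category == "ambiguous"))
})

test_that("duplicate-sequence reads are ambiguous until the threshold drops", {
  set.seed(13)
  s <- random_seq(20)
  lib <- make_lib(c(s, s, random_seq(20)), genes = c("gA", "gB", "gC"))
  idx <- build_index(lib)
  trimmed <- tibble::tibble(
    read_id = paste0("r", 1:5), status = "extracted",
    candidate = s, adapter_end = 22L
  )
  at2 <- classify_reads(trimmed, idx, ambiguity_threshold = 2)
  expect_true(all(at2$category == "ambiguous"))

  at0 <- classify_reads(trimmed, idx, ambiguity_threshold = 0)
  expect_true(all(at0$category == "tolerated"))
  # deterministic assignment to the lexicographically smallest id
  expect_true(all(at0$assigned_sgrna == "sg01"))
})
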