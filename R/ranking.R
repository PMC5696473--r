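#' Normalized p-value ranks over the sgRNA universe
#'
#' @param pvalues p-values for every library sgRNA.
#' @return `rank(p) / N` with average ranks for ties; values in (0, 1].
#' @export
normalized_ranks <- function(pvalues) {
  rank(pvalues, ties.method = "average") / length(pvalues)
}

#' alpha-RRA score of one gene
#'
#' Robust rank aggregation, adjusted by a significance gate: only the
#' gene's sgRNAs with p-value below `p0` contribute. Their normalized
#' ranks r_(1) <= ... <= r_(k) are compared with the order statistics of
#' k uniform draws: `rho = min_j P(Beta(j, n - j + 1) <= r_(j))`, where
#' n is the gene's total sgRNA count. Genes with no significant sgRNA
#' score exactly 1.
#'
#' @param ranks the gene's normalized ranks (from [normalized_ranks]).
#' @param pvalues the gene's sgRNA p-values, same order.
#' @param p0 sgRNA significance cutoff (default 0.05).
#' @return The score rho in (0, 1].
#' @export
arra_gene_score <- function(ranks, pvalues, p0 = 0.05) {
  stopifnot(length(ranks) == length(pvalues), p0 > 0, p0 <= 1)
  n <- length(ranks)
  r <- sort(ranks[pvalues < p0])
  k <- length(r)
  if (k == 0) return(1.0)
  min(pbeta(r, seq_len(k), n - seq_len(k) + 1))
}

# Vectorized rho over a size class: R and P are (genes x s) matrices of
# normalized ranks and p-values. Non-significant slots are pushed to rank
# 1 so that, after a row sort, the significant ranks occupy the leading
# positions with the right order-statistic index and the padding
# contributes pbeta(1, .) = 1.
rho_rows <- function(R, P, p0) {
  s <- ncol(R)
  R[P >= p0] <- 1
  o <- order(row(R), R)
  Rs <- matrix(R[o], nrow = nrow(R), ncol = s, byrow = TRUE)
  B <- pbeta(as.vector(Rs),
             rep(seq_len(s), each = nrow(R)),
             rep(s - seq_len(s) + 1, each = nrow(R)))
  B <- matrix(B, nrow = nrow(R))
  out <- B[, 1]
  for (j in seq_len(s)[-1]) out <- pmin(out, B[, j])
  # an all-padding row is a gene with no significant sgRNA: score 1
  out[rowSums(P < p0) == 0] <- 1
  out
}

#' alpha-RRA gene ranking with permutation p-values
#'
#' Computes per-gene alpha-RRA scores from per-sgRNA p-values, then
#' estimates their null distribution by randomly reassigning sgRNA
#' p-values to gene slots (`n_permutations` times, gene sizes
#' preserved). Null scores are pooled across genes of the same sgRNA
#' count, since genes with different guide counts have different score
#' distributions. The permutation p-value uses add-one smoothing,
#' `(1 + #null <= rho) / (1 + #null)`, and is BH-adjusted over genes.
#' The ranking sorts by FDR (ascending), then score (ascending, i.e.
#' -log score descending), then gene id.
#'
#' @param sgrna_results tibble with `sgrna_id`, `gene_id`, `p_value`
#'   covering the whole library (e.g. from [test_sample]).
#' @param p0 sgRNA significance cutoff (default 0.05).
#' @param n_permutations number of permutations (default 1000).
#' @param seed integer seed for the permutation RNG (optional).
#' @return Tibble of class `gene_ranking`: `gene_id`, `n_sgrnas`,
#'   `n_significant`, `rho`, `neg_log10_rho`, `perm_p`, `fdr`, `rank`.
#' @export
arra_ranking <- function(sgrna_results, p0 = 0.05, n_permutations = 1000,
                         seed = NULL) {
  stopifnot(all(c("sgrna_id", "gene_id", "p_value") %in%
                  names(sgrna_results)),
            p0 > 0, p0 <= 1, n_permutations >= 1)
  p <- sgrna_results$p_value
  r <- normalized_ranks(p)
  gene <- sgrna_results$gene_id

  slots <- split(seq_along(gene), gene)
  sizes <- lengths(slots)

  observed <- tibble::tibble(
    gene_id = names(slots),
    n_sgrnas = unname(as.integer(sizes)),
    n_significant = unname(vapply(slots, function(i) sum(p[i] < p0),
                                  integer(1))),
    rho = unname(vapply(slots, function(i) arra_gene_score(r[i], p[i], p0),
                        numeric(1)))
  )

  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }

  # null scores stratified by gene size; slots refilled from a shuffled
  # (rank, p) pairing each round
  size_classes <- sort(unique(sizes))
  null_scores <- setNames(vector("list", length(size_classes)),
                          as.character(size_classes))
  n <- length(p)
  slot_idx <- lapply(size_classes, function(s) {
    which_genes <- which(sizes == s)
    matrix(unlist(slots[which_genes]), ncol = s, byrow = TRUE)
  })
  names(slot_idx) <- as.character(size_classes)

  for (cls in as.character(size_classes)) {
    null_scores[[cls]] <- vector("list", n_permutations)
  }
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(n)
    rp <- r[perm]; pp <- p[perm]
    for (cls in as.character(size_classes)) {
      idx <- slot_idx[[cls]]
      R <- matrix(rp[idx], nrow = nrow(idx))
      P <- matrix(pp[idx], nrow = nrow(idx))
      null_scores[[cls]][[b]] <- rho_rows(R, P, p0)
    }
  }
  null_scores <- lapply(null_scores, function(x)
    sort(unlist(x, use.names = FALSE)))

  perm_p <- vapply(seq_len(nrow(observed)), function(g) {
    null <- null_scores[[as.character(observed$n_sgrnas[g])]]
    (1 + findInterval(observed$rho[g], null)) / (1 + length(null))
  }, numeric(1))

  out <- observed |>
    dplyr::mutate(neg_log10_rho = -log10(.data$rho),
                  perm_p = perm_p,
                  fdr = bh_adjust(perm_p))
  out <- rank_genes(out)
  structure(out, class = c("gene_ranking", class(out)))
}

#' Sort a gene ranking table
#'
#' Stable two-level sort: FDR ascending, then score rho ascending
#' (equivalently -log rho descending), then gene id as a deterministic
#' tiebreak; adds a `rank` column.
#'
#' @param records tibble with `fdr`, `rho`, `gene_id`.
#' @return The sorted tibble with `rank` added.
#' @export
rank_genes <- function(records) {
  records |>
    dplyr::arrange(.data$fdr, .data$rho, .data$gene_id) |>
    dplyr::mutate(rank = dplyr::row_number())
}
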