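# Independent brute-force oracles used across the suite. These are
# deliberately naive reimplementations (full DP matrices, exhaustive
# window enumeration, textbook formulas) kept separate from the package
# code paths they check.

# Full Smith-Waterman DP with affine gaps (gap of length k costs
# open + k * extend), plain R, no pruning.
sw_oracle <- function(a, b, match = 2, mismatch = 6, gap_open = 5,
                      gap_extend = 3) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in a
  F <- matrix(NEG, n + 1, m + 1)  # gap in b
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1] && a[i - 1] != "N") match else -mismatch
      E[i, j] <- max(E[i, j - 1] - gap_extend,
                     H[i, j - 1] - gap_open - gap_extend)
      F[i, j] <- max(F[i - 1, j] - gap_extend,
                     H[i - 1, j] - gap_open - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Best semi-global adapter occurrence by exhaustive window enumeration:
# Levenshtein distance (utils::adist) of the adapter against every read
# substring; returns the minimum error count within budget, or NA.
locate_oracle_errors <- function(read, adapter, max_err) {
  n <- nchar(read)
  best <- Inf
  for (s in 0:n) {
    for (e in s:n) {
      d <- utils::adist(adapter, substr(read, s + 1, e))[1, 1]
      if (d < best) best <- d
    }
  }
  if (best <= max_err) best else NA_integer_
}

# Textbook BH step-up: p_(i) * n / i, min over the tail, capped at 1.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# NB/Poisson tail by exhaustive PMF summation; the upper tail is summed
# term by term (not via 1 - lower) to keep tiny tails accurate.
nb_tail_oracle <- function(c, mu, v, direction, upper = 50000) {
  pmf <- if (v <= mu) {
    function(k) stats::dpois(k, mu)
  } else {
    r <- mu^2 / (v - mu)
    function(k) stats::dnbinom(k, size = r, mu = mu)
  }
  if (direction == "enrichment") {
    q <- ceiling(c)
    if (q <= 0) 1 else sum(pmf(q:upper))
  } else {
    sum(pmf(0:floor(c)))
  }
}

random_library <- function(n_genes, sgrnas_per_gene = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_genes * sgrnas_per_gene
  seqs <- character(0)
  while (length(seqs) < n) {
    seqs <- unique(c(seqs, replicate(n, paste0(
      sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""))))
  }
  sgrna_library(tibble::tibble(
    sgrna_id = sprintf("sg%03d", seq_len(n)),
    gene_id = rep(sprintf("g%03d", seq_len(n_genes)),
                  each = sgrnas_per_gene),
    sequence = seqs[seq_len(n)]
  ), adapter = "TTGTGGAAAGGACGAAACACCG")
}

random_seq <- function(len) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, positions, bases = NULL) {
  ch <- strsplit(s, "")[[1]]
  for (k in seq_along(positions)) {
    i <- positions[k]
    b <- if (is.null(bases)) setdiff(c("A", "C", "G", "T"), ch[i])[1] else
      bases[k]
    ch[i] <- b
  }
  paste0(ch, collapse = "")
}
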