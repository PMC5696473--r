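#' Select sgRNAs for sample clustering
#'
#' `variance` mode takes the `n_top` sgRNAs with the highest variance
#' across samples; `abundance` / `depletion` modes take the `n_top`
#' largest / smallest sgRNAs per sample and return the union of those
#' per-sample sets. Ties are broken by `sgrna_id` for determinism.
#'
#' @param m normalized count matrix with >= 2 samples.
#' @param n_top number of sgRNAs per selection (default 25).
#' @param selection `"variance"`, `"abundance"` or `"depletion"`.
#' @return Character vector of selected `sgrna_id`s.
#' @export
select_top_sgrnas <- function(m, n_top = 25,
                              selection = c("variance", "abundance",
                                            "depletion")) {
  selection <- match.arg(selection)
  samples <- sample_cols(m)
  stopifnot(length(samples) >= 2, n_top >= 2, n_top <= nrow(m))
  vals <- as.matrix(m[samples])

  if (selection == "variance") {
    v <- apply(vals, 1, var)
    ord <- order(-v, m$sgrna_id)
    return(m$sgrna_id[ord[seq_len(n_top)]])
  }
  sel <- lapply(samples, function(s) {
    key <- if (selection == "abundance") -m[[s]] else m[[s]]
    ord <- order(key, m$sgrna_id)
    m$sgrna_id[ord[seq_len(n_top)]]
  })
  sort(unique(unlist(sel)))
}

#' Hierarchically cluster samples
#'
#' Agglomerative clustering of the sample columns on `log10(count + 1)`
#' transformed values of the selected sgRNAs; Euclidean distance and
#' complete linkage by default (the usual heatmap defaults). The counts
#' span orders of magnitude, hence the log transform.
#'
#' @param m normalized count matrix.
#' @param sgrna_ids rows to cluster on (e.g. from [select_top_sgrnas]);
#'   all rows when NULL.
#' @param distance distance metric passed to [stats::dist()].
#' @param linkage linkage method passed to [stats::hclust()].
#' @return Object of class `sample_clustering`: list with the `hclust`
#'   fit and `merges`, a tibble (step, left, right, height) where
#'   negative labels denote singleton samples and positive labels prior
#'   merge steps.
#' @export
cluster_samples <- function(m, sgrna_ids = NULL, distance = "euclidean",
                            linkage = "complete") {
  samples <- sample_cols(m)
  stopifnot(length(samples) >= 2)
  sub <- if (is.null(sgrna_ids)) m else
    m[match(sgrna_ids, m$sgrna_id), , drop = FALSE]
  vals <- log10(t(as.matrix(sub[samples])) + 1)
  rownames(vals) <- samples
  hc <- hclust(dist(vals, method = distance), method = linkage)
  merges <- tibble::tibble(
    step = seq_len(nrow(hc$merge)),
    left = label_merge(hc, hc$merge[, 1]),
    right = label_merge(hc, hc$merge[, 2]),
    height = hc$height
  )
  structure(list(hclust = hc, merges = merges, samples = samples),
            class = "sample_clustering")
}

label_merge <- function(hc, col) {
  out <- character(length(col))
  neg <- col < 0
  out[neg] <- hc$labels[-col[neg]]
  out[!neg] <- paste0("step", col[!neg])
  out
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("sample clustering over", length(x$samples), "samples\n")
  print(x$merges)
  invisible(x)
}

#' Tidy a sample clustering
#'
#' @param x a `sample_clustering`.
#' @param ... unused.
#' @return The merge table tibble.
#' @export
tidy.sample_clustering <- function(x, ...) x$merges
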