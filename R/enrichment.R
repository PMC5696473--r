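#' Fit the negative-binomial mean-variance model on control replicates
#'
#' Normalized counts under the control condition are modeled as negative
#' binomial with the quadratic mean-variance law `sigma^2 = mu + D mu^2`.
#' Per sgRNA, `mu` is the mean and `sigma^2` the sample variance (n - 1
#' denominator) across control replicates; the dispersion D is the
#' through-origin least-squares slope of `sigma^2 - mu` on `mu^2` over
#' sgRNAs with `mu > 0`, clamped at 0 (a negative slope means
#' underdispersion the NB cannot express, so the model falls back to
#' Poisson). The fitted model variance is `mu + D mu^2`.
#'
#' @param control normalized count matrix restricted to >= 2 control
#'   columns, or a full matrix plus `controls` naming them.
#' @param controls optional character vector of control sample columns.
#' @return Object of class `dispersion_model`: a list with `D`,
#'   `n_controls` and a per-sgRNA tibble (`sgrna_id`, `gene_id`, `mu`,
#'   `var`, `model_var`).
#' @export
estimate_dispersion <- function(control, controls = NULL) {
  samples <- if (is.null(controls)) sample_cols(control) else controls
  if (length(samples) < 2) {
    stop("dispersion estimation needs >= 2 control samples; ",
         "with one control only fold-changes can be reported")
  }
  vals <- as.matrix(control[samples])
  mu <- rowMeans(vals)
  v <- apply(vals, 1, var)

  pos <- mu > 0
  x <- mu[pos]^2
  y <- v[pos] - mu[pos]
  D <- if (sum(x^2) > 0) max(0, sum(x * y) / sum(x^2)) else 0

  structure(list(
    D = D,
    n_controls = length(samples),
    normalization = count_normalization(control),
    sgrnas = tibble::tibble(
      sgrna_id = control$sgrna_id,
      gene_id = control$gene_id,
      mu = mu,
      var = v,
      model_var = mu + D * mu^2
    )
  ), class = "dispersion_model")
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat("NB dispersion model: D =", format(x$D, digits = 4), "over",
      nrow(x$sgrnas), "sgRNAs,", x$n_controls, "controls\n")
  invisible(x)
}

#' Tidy a dispersion model
#'
#' @param x a `dispersion_model`.
#' @param ... unused.
#' @return The per-sgRNA tibble of means and variances.
#' @export
tidy.dispersion_model <- function(x, ...) x$sgrnas

#' One-line summary of a dispersion model
#'
#' @param x a `dispersion_model`.
#' @param ... unused.
#' @return One-row tibble with `D`, `n_sgrnas`, `n_controls`.
#' @export
glance.dispersion_model <- function(x, ...) {
  tibble::tibble(D = x$D, n_sgrnas = nrow(x$sgrnas),
                 n_controls = x$n_controls)
}

#' Negative-binomial tail p-value
#'
#' Tests an observed normalized count against NB(mu, var). The NB is
#' parameterized by size `r = mu^2 / (var - mu)` with mean `mu`; when
#' `var == mu` the Poisson tail is used. Normalized counts are bracketed
#' to integers conservatively: enrichment tests `P(X >= ceiling(c))`,
#' depletion `P(X <= floor(c))`. A zero mean gives p = 1 under depletion;
#' enrichment at zero mean is handled upstream by flooring the mean.
#'
#' @param c observed count(s).
#' @param mu model mean(s), > 0 (0 allowed for depletion).
#' @param var model variance(s), >= mu.
#' @param direction `"enrichment"` or `"depletion"`.
#' @return p-values in (0, 1\].
#' @export
nb_tail_pvalue <- function(c, mu, var, direction = c("enrichment",
                                                     "depletion")) {
  direction <- match.arg(direction)
  stopifnot(all(var >= mu - 1e-12))
  n <- max(length(c), length(mu), length(var))
  c <- rep_len(c, n); mu <- rep_len(mu, n); var <- rep_len(var, n)

  p <- numeric(n)
  pois <- var <= mu * (1 + 1e-12)
  if (direction == "enrichment") {
    q <- ceiling(c) - 1
    p[pois] <- ppois(q[pois], lambda = mu[pois], lower.tail = FALSE)
    if (any(!pois)) {
      r <- mu[!pois]^2 / (var[!pois] - mu[!pois])
      p[!pois] <- pnbinom(q[!pois], size = r, mu = mu[!pois],
                          lower.tail = FALSE)
    }
    # P(X >= 0) is 1 regardless of the model
    p[ceiling(c) <= 0] <- 1
  } else {
    q <- floor(c)
    p[pois] <- ppois(q[pois], lambda = mu[pois])
    if (any(!pois)) {
      r <- mu[!pois]^2 / (var[!pois] - mu[!pois])
      p[!pois] <- pnbinom(q[!pois], size = r, mu = mu[!pois])
    }
    p[mu == 0] <- 1
  }
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control with monotone enforcement,
#' capped at 1.
#'
#' @param pvalues vector of p-values in (0, 1\].
#' @return FDR values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  p.adjust(pvalues, method = "BH")
}

#' Test one treatment sample against the control model
#'
#' Per sgRNA: fold-change of the treatment count to the control mean
#' (with a pseudocount when either side is zero), a one-sided NB tail
#' p-value in the screen's direction, and BH-FDR over the whole sgRNA
#' set. Enriched sgRNAs with zero control mean are tested against the
#' smallest positive control mean in the model and flagged
#' (`mu_floored`), since the NB is undefined at mean 0; flooring keeps
#' the strongest hits in the ranking instead of dropping them.
#'
#' @param m normalized count matrix containing the treatment column.
#' @param sample treatment sample column name.
#' @param model a [estimate_dispersion] fit on the matching controls.
#' @param direction `"enrichment"` or `"depletion"` (fixed per screen).
#' @param pseudocount added to both numerator and denominator of the
#'   fold-change when either is zero (default 1; exact ratio otherwise).
#' @return Tibble: `sgrna_id`, `gene_id`, `control_mean`,
#'   `treatment_count`, `fold_change`, `p_value`, `fdr`, `mu_floored`,
#'   `direction`.
#' @export
test_sample <- function(m, sample, model,
                        direction = c("enrichment", "depletion"),
                        pseudocount = 1) {
  direction <- match.arg(direction)
  stopifnot(inherits(model, "dispersion_model"),
            sample %in% sample_cols(m))
  if (!identical(m$sgrna_id, model$sgrnas$sgrna_id)) {
    stop("count matrix and dispersion model cover different sgRNAs")
  }
  ci <- m[[sample]]
  mu <- model$sgrnas$mu
  mvar <- model$sgrnas$model_var

  eps <- ifelse(ci > 0 & mu > 0, 0, pseudocount)
  fc <- (ci + eps) / (mu + eps)

  floored <- direction == "enrichment" & mu == 0 & ci > 0
  mu_test <- mu
  if (any(floored)) {
    mu_min <- min(mu[mu > 0])
    mu_test[floored] <- mu_min
  }
  mvar_test <- mu_test + model$D * mu_test^2

  pv <- nb_tail_pvalue(ci, mu_test, mvar_test, direction)
  tibble::tibble(
    sgrna_id = m$sgrna_id,
    gene_id = m$gene_id,
    control_mean = mu,
    treatment_count = ci,
    fold_change = fc,
    p_value = pv,
    fdr = bh_adjust(pv),
    mu_floored = floored,
    direction = direction
  )
}

#' Fold-change-only records for single-control runs
#'
#' With fewer than two control replicates no variance can be estimated,
#' so only fold-changes are reported.
#'
#' @inheritParams test_sample
#' @param control control sample column name.
#' @return Tibble without `p_value`/`fdr` columns.
#' @export
fold_change_only <- function(m, sample, control, pseudocount = 1) {
  stopifnot(sample %in% sample_cols(m), control %in% sample_cols(m))
  ci <- m[[sample]]
  mu <- m[[control]]
  eps <- ifelse(ci > 0 & mu > 0, 0, pseudocount)
  tibble::tibble(
    sgrna_id = m$sgrna_id,
    gene_id = m$gene_id,
    control_mean = mu,
    treatment_count = ci,
    fold_change = (ci + eps) / (mu + eps)
  )
}

#' Pairwise correlation between replicate samples
#'
#' Pearson and Spearman coefficients for every pair of the given
#' columns, computed on `log10(count + 1)`. A constant column has no
#' defined correlation and is reported as NA.
#'
#' @param m normalized count matrix.
#' @param samples >= 2 sample columns of one condition.
#' @return Tibble: `sample_a`, `sample_b`, `pearson`, `spearman`.
#' @export
replicate_correlation <- function(m, samples = sample_cols(m)) {
  stopifnot(length(samples) >= 2)
  pairs <- utils::combn(samples, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- log10(m[[pairs[1, k]]] + 1)
    b <- log10(m[[pairs[2, k]]] + 1)
    const <- sd(a) == 0 || sd(b) == 0
    tibble::tibble(
      sample_a = pairs[1, k],
      sample_b = pairs[2, k],
      pearson = if (const) NA_real_ else cor(a, b),
      spearman = if (const) NA_real_ else cor(a, b, method = "spearman")
    )
  })
}
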