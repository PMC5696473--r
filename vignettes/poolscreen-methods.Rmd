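---
title: "Models and methods behind poolscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poolscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
```

poolscreen analyzes pooled CRISPR/Cas9 screens: populations of cells,
each carrying one integrated sgRNA, are put under selection, and shifts
in sgRNA abundance between control and treatment samples reveal gene
function. This vignette documents the models, the tunable parameters,
the numerical conventions, and the choices that were genuinely open —
in enough detail that every number the pipeline prints can be traced to
a formula.

## Read extraction

Amplicon reads have the layout *stagger + adapter + 20 nt protospacer
+ tail*. Staggers are variable-length spacers added so that pooled
samples do not read the same base at the same cycle; as a consequence
the protospacer's position varies between reads and samples, and fixed
position trimming fails. poolscreen instead locates the adapter itself
in each read by semi-global alignment: the adapter must be consumed in
full (no overhang past the read's 5′ end), the read flanks are free,
and substitutions and indels each cost one error. An occurrence is
accepted if its error count is at most `floor(error_rate × adapter
length)`; `error_rate` defaults to 0.1. Ties go to the occurrence with
the fewest errors, then the leftmost start, so repeated adapter-like
sequence downstream cannot displace the true hit. The candidate is the
first 20 bases after the adapter; remainders shorter than `min_length`
(default 20) give status `too_short` rather than a padded candidate.

Two conventions worth noting: `N` bases never match (conservative — an
uncalled base cannot corroborate the adapter), and base qualities are
carried through but never consulted; extraction is sequence-only.

## Alignment and classification

Candidates are scored against the library by Smith–Waterman local
alignment with affine gaps: match +2, mismatch −6, a gap of length $k$
costs $5 + 3k$. Under these defaults a perfect 20-mer scores exactly
40, which makes the default matching threshold self-documenting. A
seed prefilter (all 13 overlapping 8-mers of the candidate, hashed
against the library) limits full scoring to entries sharing at least
one seed. The prefilter is exact for the default perfect-match
threshold — an exact match trivially shares every seed — and for any
candidate within two mismatches of an entry (pigeonhole: three
mismatches are needed to break all 8-mer runs in a 20-mer). When the
matching threshold is lowered far enough that 3+-error alignments
matter, the prefilter can in principle miss a sub-perfect best entry;
the test suite checks score equality against a full-matrix oracle
wherever a seed exists and documents this boundary.

Classification uses the two best scores, primary `AS` and secondary
`XS` (reported only when at least two matched bases support it):

| condition | category |
|---|---|
| no alignment, or `AS` < θ_m | failed |
| `XS` present and `AS − XS` < θ_a | ambiguous |
| `XS` present and `AS − XS` ≥ θ_a | tolerated |
| no `XS` | unique |

θ_m defaults to the perfect score (40), θ_a to 2. Only unique and
tolerated reads are counted. Ambiguity matters in practice: genome-wide
libraries contain thousands of entries sharing identical protospacers,
and every read matching one of them matches all of them equally well.
At θ_a = 2 such reads are discarded; at θ_a = 0 they are kept and
assigned. Random assignment among the tied entries would be unbiased; poolscreen
assigns to the lexicographically smallest sgrna_id instead, trading a
small bias within the duplicated group for bit-for-bit reproducibility.
Reverse-complement matching is not attempted — the amplicon protocol
fixes the read orientation.

## Quantification

Gene counts are the sums of their sgRNAs' counts. The optional noise
cutoff is expressed in cpm but applied to **raw** counts before
normalization, so the cutoff's meaning does not depend on the
normalization method chosen afterwards. Three normalizations are
offered: `cpm` (`count / column total × 10⁶`), `total` (column scaled
to the mean column total, preserving the grand mean), and
`size-factor` — the median-ratio method, where each sample is divided
by the median of its counts' ratios to per-sgRNA geometric means,
computed over sgRNAs with strictly positive counts in every sample.
Size factors are robust to a few dominant sgRNAs, but require at least
one everywhere-positive sgRNA; the error message suggests cpm/total
otherwise.

Per-sample diagnostics use the population standard deviation (divide
by n) and the Gini coefficient via the sorted-rank identity
$G = \frac{2\sum_i i\,x_{(i)}}{n\sum_i x_i} - \frac{n+1}{n}$, with an
all-zero sample defined as $G = 0$. A healthy library sits near
uniform (low Gini); selection drives Gini up as a few sgRNAs take over
— visible in the worked example, where treatment samples have markedly
higher Gini and standard deviation than controls.

## The negative-binomial test

Control counts per sgRNA are modeled as NB with the quadratic
mean–variance law $\sigma^2 = \mu + D\mu^2$; $D = 0$ recovers Poisson.
Per sgRNA, $\mu_i$ is the mean and $\sigma_i^2$ the sample variance
(n−1 denominator — a documented choice, as either denominator is
defensible for a descriptive fit) across control replicates. $D$ is
estimated by least squares **through the origin** of
$y_i = \sigma_i^2 - \mu_i$ on $x_i = \mu_i^2$, the minimal faithful
regression form of the variance law, over sgRNAs with $\mu_i > 0$, and
clamped at 0 since a negative $D$ (underdispersion) is outside the NB
family. The fitted variance $\hat\sigma_i^2 = \mu_i + D\mu_i^2$ then
parameterizes NB$(\mu_i, \hat\sigma_i^2)$ via size
$r = \mu^2/(\hat\sigma^2 - \mu)$.

A treatment count $c_i$ gets the one-sided tail in the screen's
direction: $P(X \ge \lceil c_i \rceil)$ for enrichment,
$P(X \le \lfloor c_i \rfloor)$ for depletion — normalized counts are
non-integer, and bracketing outward is conservative in both directions.
When $\hat\sigma^2 = \mu$ the Poisson tail is used. Degenerate means:
depletion at $\mu_i = 0$ gives p = 1 (nothing to lose); enrichment at
$\mu_i = 0$ with $c_i > 0$ floors $\mu$ at the smallest positive
control mean and flags the record (`mu_floored`) — the NB is undefined
at mean 0, and silently dropping what are often the strongest hits
would be worse than testing them against the most lenient defined
null. Fold-changes use a pseudocount of 1 only when either side is
zero. P-values are BH-adjusted across the sgRNA set
(`stats::p.adjust`). At least two control replicates are required for
any of this; with one control the pipeline reports fold-changes only.

## αRRA gene ranking

All library sgRNAs are ranked by p-value (average ranks on ties) and
normalized to $r_i = \mathrm{rank}(p_i)/N$. For a gene with $n$ guides
of which $k$ pass the significance gate $p < P_0$ (default 0.05), the
sorted significant ranks $r_{(1)} \le \dots \le r_{(k)}$ are compared
to uniform order statistics:
$\rho = \min_{j \le k} P\!\left(\mathrm{Beta}(j,\, n-j+1) \le
r_{(j)}\right)$, and $\rho = 1$ exactly when $k = 0$. The score asks:
how improbably small is the most extreme prefix of this gene's guide
ranks if guides were assigned at random?

Null calibration reassigns sgRNA p-values to gene slots at random
(`n_permutations` = 1000 by default) and pools the resulting scores
**within gene-size classes** — a 6-guide gene and a 2-guide gene have
different null laws for $\rho$, and pooling across sizes would
miscalibrate both. The permutation p-value uses add-one smoothing,
$(1 + \#\{\rho_{null} \le \rho\})/(1 + \#\rho_{null})$, so it is never
zero; BH-FDR is applied across genes, and the final sort is FDR
ascending, then $\rho$ ascending, then gene id as a deterministic
tiebreak. The permutation stream is driven by a single integer seed
recorded in the run manifest; rerunning with the same seed reproduces
the ranking byte for byte. The inner scorer is vectorized (rows sorted
with non-significant slots pushed to rank 1, where the Beta CDF
contributes 1), and the suite replays small cases against the scalar
definition to pin the two implementations together.

The significance gate defaults to $P_0 = 0.05$, the standard αRRA
convention, and is configurable.

## Clustering

Samples are clustered on the `n_top` (default 25) most variable
sgRNAs, or on the union of per-sample top/bottom-`n_top` sets in
abundance/depletion mode, using Euclidean distance and complete
linkage on $\log_{10}(x+1)$-transformed columns. The log transform is
deliberate: raw counts span orders of magnitude and untransformed
Euclidean distances would be dominated by the few largest sgRNAs.
The canonical output is the merge table (step, left, right, height),
which is testable text; heatmap rendering is left to the user's
plotting of the returned `hclust` object.

## The synthetic screen generator

`simulate_library()` draws distinct random 20-mers (optionally with
deliberate duplicated sequences to exercise ambiguity handling);
`simulate_counts()` draws NB counts with per-sgRNA lognormal baseline
means (sdlog 0.3 around `baseline_mean`, mimicking uneven library
representation) and multiplies spiked genes' means by their fold
effect, using the same (mean, variance) → (size, mu)
parameterization as the test module so generator and estimator share
one convention; `counts_to_fastq()` emits each count as a read with a
random stagger (0–7 nt by default), the library adapter, the
protospacer and a fixed tail, with optional per-base substitution
errors, in shuffled order.

Default study conditions used by the end-to-end suite: 100 genes × 6
sgRNAs (six guides per gene being the common genome-wide design),
baseline mean 200, dispersion 0.2, two controls and two treatments,
one gene spiked at fold 50, staggers 0–7, and zero sequencing error
for exact round-trip accounting. Dispersion-recovery checks use 2 004
sgRNAs and four controls at baseline 300 across D ∈ {0, 0.2, 0.5}.
These sizes keep a full run in seconds while leaving enough signal to
separate the spiked gene decisively; they are stated here so results
can be reproduced exactly.

What the generator does **not** emulate — and hence what passing tests
cannot show about real data: PCR amplification bias, position- and
quality-dependent error profiles, indel sequencing errors inside the
protospacer, adapter contamination, cross-sample index hopping, and
biological off-target effects. Round-trip count equality holds only at
zero simulated error; with errors, recovery is deliberately lossy at
perfect-match stringency, which the suite asserts as an inequality.

## Known limitations

- No per-sgRNA dispersion shrinkage — a single global D is fit; genes with few, noisy guides benefit less than they
  would under an empirical-Bayes variance model.
- One-sided tests only, direction fixed per run by screen type.
- Single-end amplicon reads only; no 3′ adapter or quality trimming.
- The seed prefilter's exactness guarantee weakens below two mismatches
  worth of matching threshold, as described above.
- Permutation p-values are bounded below by 1/(1 + total null scores);
  genes at the floor are reported at that resolution, not at zero.
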