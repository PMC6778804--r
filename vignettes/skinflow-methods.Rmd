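---
title: "Modeling and classifying two-layer skin transcriptomes with skinflow"
author: "skinflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and classifying two-layer skin transcriptomes with skinflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinflow)
```

# The problem

Embryonic zebrafish skin is a bilayer: an outer periderm and an inner
layer of basal cells. Sorting these populations (together with nonskin
reference populations) at three developmental timepoints — the 20-somite
stage (20 SS, before the layers can be sorted apart), 52 hpf and 72 hpf —
and sequencing each population in duplicate yields a 12-condition,
23-sample bulk RNA-seq design (every condition has two biological
replicates except a single replicate of the second nonskin reference at
52 hpf). The question downstream of quantification is: per gene, is it a
skin gene at all, and if so, is it shared between the layers or specific
to one of them — and how does that status change over developmental time?

`skinflow` implements the downstream statistics for this design:

1. per-gene, per-condition normal expression models on the log2 scale,
   with variance partitioned into a technical component (from quantifier
   bootstrap resamples) and a biological component (from replicates,
   with empirical-Bayes shrinkage);
2. fold-change-threshold ordering probabilities that classify each gene
   per timepoint and concatenate the categories into a "flow";
3. hypergeometric gene-set enrichment over flows, an expressed-gene
   filter, and a skin/layer-specificity gene ranking;
4. experiment-level clustering (centered unscaled PCA, complete-linkage
   Chebyshev clustering, optimal leaf ordering);
5. a synthetic-data generator that emulates the full design so the
   pipeline is testable end-to-end without any external download.

# The expression model

Expression of gene $g$ under condition $c$ is modeled on the log2 scale
as $\mathrm{Normal}(m_{gc},\, v^{\mathrm{tech}}_{gc} +
v^{\mathrm{bio}}_{gc})$, so the condition mean has standard error
$\mathrm{se}_{gc} = \sqrt{(v^{\mathrm{tech}}_{gc} +
v^{\mathrm{bio}}_{gc})/n_c}$ with $n_c$ replicates.

**Normalization.** Size factors are median-of-ratios against the
per-gene geometric-mean reference, computed over genes with positive
counts in every sample, and rescaled to geometric mean 1. This is the
standard for expected counts, is scale-equivariant, and is idempotent
(normalizing a normalized matrix returns unit factors).

**Transform.** $\log_2(x + 0.5)$. The 0.5 pseudo-count avoids
$\log 0$ while distorting moderate counts very little: the
expressed-gene threshold of 2.5 on this scale corresponds to
$2^{2.5} - 0.5 \approx 5.2$ normalized counts, i.e. roughly 5.7 when the
offset is ignored — at that magnitude the difference is immaterial.

**Technical variance.** Each sample carries a genes × B matrix of
bootstrap count vectors (B = 1,000 in the emulated design) from
probabilistic quantification. Each matrix is normalized by the sample's
size factor and transformed; the per-gene variance across the B columns
(unbiased, computed on centered values to avoid cancellation) estimates
the assay noise of one observation. Condition-level technical variance
averages the condition's per-sample variances — equal weight per
replicate, robust to unequal bootstrap depth — rather than pooling
columns.

**Biological variance and shrinkage.** With $n_c \ge 2$,
$v^{\mathrm{bio,raw}}_{gc} = \max(0,\, s^2_{gc} -
v^{\mathrm{tech}}_{gc})$, where $s^2$ is the replicate variance of the
transformed values; the floor is needed because finite-sample variance
decomposition can go negative. Raw values with one degree of freedom are
extremely noisy, so they are shrunk toward a mean-variance trend
$t(m)$: the blend is geometric,
$$v^{\mathrm{bio}} = \exp\!\big(w \log(v^{\mathrm{bio,raw}} +
\varepsilon_0) + (1 - w)\, t(m)\big) - \varepsilon_0,$$
with $w = (n-1)/(n-1+n_0)$, prior weight $n_0 = 3$ and regularizer
$\varepsilon_0 = 0.01$. Single-replicate conditions take the trend value
($w = 0$). Two numerical choices matter here and were made for
unbiasedness at low degrees of freedom:

* the trend is smoothed on the **variance scale** (lowess of
  $v^{\mathrm{bio,raw}} + \varepsilon_0$ against $m$, then logged), not
  on the log-variance scale: for $\chi^2_1$-distributed raw variances,
  $E[\log s^2]$ sits about 1.27 below $\log \sigma^2$, and a log-scale
  trend would propagate that bias into every shrunken value;
* lowess runs **without robustness iterations** (`iter = 0`): the
  robust fit tracks the median of the skewed raw variances, roughly
  0.45 of their mean.

With these choices, the across-gene mean of $v^{\mathrm{bio}}$ recovers
a simulated dispersion of $\sigma^2 = 0.0625$ to within about 8% at
2,000 genes (the residual downward bias is the Jensen penalty of the
geometric blend); the test suite asserts recovery within 15%.

**Profile summaries.** `conditionSummary()` reports, per condition,
the mean and the interval $m \pm 2\,\mathrm{se}$ — approximately a 95%
confidence interval for the condition mean, matching the error-bar
convention of per-gene profile plots.

# Category rules and flows

All rules are driven by two tunable constants, held in
`flowThresholds()`:

* $\theta = \log_2 1.5 \approx 0.585$: the fold-change threshold.
  "A significantly higher than B" is the event
  $\mu_A - \mu_B > \theta$ under the fitted normal models, i.e. a 1.5×
  fold-change-aware test rather than a point-null test.
* $\varepsilon = 0.02$: the negligibility probability. An event with
  probability $\ge \varepsilon$ is "non-negligible".

At 20 SS (layers not sorted apart), a gene is a skin gene (**S**) when
the probability that all-skin is *not* higher than the first nonskin
reference, $P(\mu_{\mathrm{skin}} - \mu_{\mathrm{nonskin}} \le \theta)$,
is below $\varepsilon$; otherwise nonskin (**N**). The same
$\varepsilon$ is reused here as the significance cutoff for symmetry
with the later timepoints.

At 52 and 72 hpf the cascade over periderm (P), basal (B) and the
second nonskin reference (N) is:

1. **N** if $P(\mu_P - \mu_N \le \theta \,\wedge\, \mu_B - \mu_N \le
   \theta) \ge \varepsilon$ — neither layer is clearly above the
   reference. The two differences share $\mu_N$, so they are positively
   correlated ($\mathrm{Cov} = \mathrm{se}_N^2$); the probability is the
   exact bivariate-normal orthant (deterministic Miwa quadrature), not a
   product of marginals. Ignoring the correlation would misclassify
   genes near the boundary.
2. otherwise **G** (general skin) if
   $P(|\mu_P - \mu_B| \le \theta) \ge \varepsilon$ — the layers are not
   clearly different.
3. otherwise **P** or **B** according to which layer is more likely
   highest ($P(\mu_P > \mu_B)$ vs 0.5). An exact tie goes to B — an
   unspecifiable edge case resolved deterministically for
   reproducibility.

The concatenation of the three categories is the gene's **flow**
(e.g. "SPP": skin at 20 SS, then periderm-preferred at both later
timepoints); the alphabets give $2 \times 4 \times 4 = 32$ possible
flows. Flow query patterns support `*` (any category) and, at the later
positions, `S` (any of G/B/P).

Whether such ordering probabilities should be computed analytically or
by sampling is a genuine design fork; `skinflow` provides both — the
analytic path as the implementation and `mcOracleClassify()` as an
independent Monte Carlo check — and the test suite requires them to
agree up to Monte Carlo error.

# Enrichment, filtering and ranking

Enrichment of a gene set in a flow pattern is the exact hypergeometric
upper tail over the model's gene universe, with fold enrichment
$(k/n)/(K/N)$. Raw p-values are the primary output; heatmap export keeps
every row and column containing at least one $p \le 10^{-4}$ and carries
$-\log_{10} p$. A Benjamini–Hochberg column is emitted alongside but
does not drive the retention rule. `foldEnrichment()` exposes the same
ratio arithmetic for printed summary counts (observed fraction vs
background count over universe).

The expressed-gene filter keeps genes whose model mean reaches 2.5
(log2 scale) in at least one condition. The gene ranking scores (1) skin
enrichment as $A - N$ (mean of the three all-skin condition means minus
the mean of the three nonskin-reference means) and (2) layer specificity
as the sum of absolute deviations from the mean over the four layer
conditions, ordering genes by the descending sum with a deterministic
gene-id tie-break. Both scores are shift-invariant, and heatmap export
centers each gene's 12 condition means on their row mean (on the linear
scale: fold change relative to the gene's geometric mean).

# Experiment clustering

Centered (feature-wise, i.e. gene-wise) unscaled PCA with samples as
observations; the first six components feed complete-linkage
hierarchical clustering under the Chebyshev (maximum-coordinate)
distance. "Centered unscaled" is read as the ordinary PCA convention of
centering features; scores are not rescaled. Leaf order is then chosen
among the $2^{n-1}$ subtree flip configurations to minimize the sum of
Chebyshev distances between adjacent leaves — an exact dynamic program
over (subtree, leftmost leaf, rightmost leaf), with a brute-force flip
enumeration retained in the tests as the oracle for small trees.
Agglomeration ties are resolved by the standard implementation's
deterministic ordering. Dendrograms export to Newick with branch
lengths equal to merge-height differences and children ordered to match
the optimized leaf order.

# The synthetic-data generator

`simConfig()` defaults encode the study conditions: 12 conditions, two
replicates each except one replicate of the second nonskin reference at
52 hpf (23 samples), B = 1,000 bootstrap vectors per sample, biological
dispersion 0.25 (log2-scale standard deviation), library factors drawn
uniformly from [0.7, 1.4] (the real libraries span about a two-fold
sequencing-depth range), and an effect size of $4\theta \approx 2.34$ —
large enough that true categories are unambiguous, so classification
errors measure pipeline noise, not truth ambiguity.

`generateTruth()` assigns each gene a flow from a configurable mix and
builds per-condition true means so that noise-free classification
reproduces the assigned flow exactly; "higher" tissues sit
`effect_size` above "lower" ones, the all-skin mean at later timepoints
is the linear-scale average of the two layer means, and the first
nonskin reference tracks the second. The default mix puts 70% of genes
in NNN and spreads the rest over stable and transitioning flows, with
zero mass on the four basal↔periderm exchange flows (SBP, SPB, NBP,
NPB) — sorted-cell data show no such exchanges, and the pipeline must
report zero genes in them at low noise.

The noise model is log-normal biological variation on the true log2
means, followed by an assay-noise step: each sample's observed counts
are one multinomial draw of the sample's rounded total over genes, and
each bootstrap column is a further multinomial resample of that total
with probabilities proportional to the observed counts. The assay draw
is what makes the generator consistent with the model it feeds: the
bootstrap spread then quantifies noise that is actually present in the
observed counts, so subtracting the technical variance from the
replicate variance is unbiased for the simulated dispersion. (Setting
`assay_noise = FALSE` produces noiseless expected counts, useful for
exercising degenerate limits.) Real quantifier Gibbs samples are
negative-binomially overdispersed and correlated across genes sharing
multi-mapping reads; the multinomial emulation captures neither, so
passing tests demonstrate correctness of the statistical machinery
under the assumed normal-on-log-scale model, not robustness to
quantifier pathologies.

Reproducibility: one R RNG stream seeded from `seed` (truth and counts
use offset seeds), so identical configurations give bit-identical
output.

# Problem sizes and test design

The shipped tests run the full-design recovery at 2,000 genes with
B = 1,000 (the emulated bootstrap depth) and assert ≥ 95% flow recovery
at dispersion 0.25, exact recovery and empty exchange flows at
dispersion 0, and dispersion-recovery monotonicity over a three-point
grid at smaller scale. Oracle-equivalence tests compare the analytic
ordering probabilities against seeded 10⁶-draw Monte Carlo estimates on
a 500-gene panel: with 1,500 probability comparisons, a handful of
3-standard-error exceedances is expected by chance even under perfect
agreement, so the suite requires at least 99% of comparisons within 3
Monte Carlo standard errors and none beyond 6 (the standard error uses
a +2 continuity guard so it is well-defined at empirical 0 or 1).
Hypergeometric tails are checked against exhaustive enumeration for
universes up to 12, and optimized leaf orders against brute-force flip
enumeration for up to 8 leaves.

The clustering invariant — the root split separates skin from nonskin
experiments — is asserted in a scenario dominated by a shared skin
program (40% of genes in flow SGG): with layer- or timepoint-restricted
programs of comparable size to the shared one, the maximum-coordinate
metric can legitimately place the 20 SS all-skin samples nearer the
nonskin cluster, so the invariant is a statement about the
strong-shared-program regime that real skin transcriptomes occupy.

# Known limitations

* The bootstrap container is HDF5 with one dataset per sample; very
  large tensors are read whole, not chunked.
* The shrinkage trend pools all gene × condition cells; a per-condition
  trend might fit heteroskedastic designs better but would leave the
  single-replicate condition without its own trend.
* No FDR control on the category calls themselves: the categories, not
  q-values, are the output surface, and the enrichment stage reports
  raw hypergeometric p-values (with a BH column) by design.
* TPMs are computed from gene-level counts and effective lengths
  supplied by the caller; no within-gene isoform-usage correction.
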