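---
title: "Methods: permutation differential expression, NMF clustering and process networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation differential expression, NMF clustering and process networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sennet)
```

This vignette is the package's own account of its statistics: the models
and their assumptions, the tunable parameters and why their defaults are
what they are, what the synthetic-data generators do and do not emulate,
the numerical choices that were genuinely open, and the known limitations.
It states no empirical result that the test suite does not itself compute.

## The two-statistic differential test

For every feature (peptide or gene) with groups A and B we compute a pair:

* `T` — the pooled-variance two-sample Student statistic on the log2 scale.
* `LMR` — the log2 median ratio, `log2(median(A)/median(B))`, with the
  medians taken on the intensity scale.  For odd group sizes (the default
  3-vs-3 design) the median commutes with `2^x`, so this equals the
  difference of log2 medians; for even sizes it does not, and the
  intensity-scale definition is used.  `LMR = 1` always means a 2-fold
  median change.

Neither statistic is referred to a parametric distribution.  Instead an
**empirical null** is built by re-labeling the sample axis: for the TMT
proteome, the six reporter channels of a contrast are permuted; for the
microarray transcriptome, the sample group labels are permuted.  A 3-vs-3
design admits only `choose(6,3) = 20` distinct relabelings, so the engine
enumerates all of them (with a warning) rather than drawing the nominal
100 or 1,000 permutations; enumeration includes the identity and, for
every relabeling, its complement, which makes the pooled LMR null exactly
symmetric.  The permuted `T` and `LMR` values of *all* features are pooled
into a single null per comparison.  Pooling is forced by arithmetic:
per-feature nulls of 20 values cannot resolve p < 0.05 (the add-one
estimator floors at 1/21), and because the identity relabeling is in every
feature's own null, a per-feature comparison could never rank the observed
statistic above its null maximum.

Empirical p-values use the add-one estimator
`p = (1 + #{null >= observed}) / (1 + n)` (two-tailed on `|T|`,
right-sided where stated), so p is never zero and never exactly
uniform — slightly conservative, which the type-I tests account for.

The **fold-change cutoff** is derived from the same null: the mean of the
absolute lower and upper percentiles of the pooled null LMR distribution
(5/95 for peptides, 2.5/97.5 for human genes, 5/95 for the yeast variant).

## Calling rules

* **DE peptide**: two-tailed empirical p(T) < 0.05, `|LMR|` strictly above
  the cutoff, and quantified (nonzero) in more than two replicates of at
  least one condition.  The replicate clause is our reading of an
  ambiguous quantification-support requirement; the alternative reading
  (condition-exclusive identification) would discard the very peptides the
  test needs.
* **DEP**: at least two unique DE peptides, all in one direction; any
  mixed-direction protein group is excluded outright.
* **DEG (human)**: the two component p-values are combined by Stouffer's
  method and the gene passes if the overall p < 0.05 and `|LMR|` exceeds
  the 2.5/97.5 cutoff.  Component two-tailed p's are converted to
  one-sided z's signed by the effect direction, `z = qnorm(1 - p/2) * s`,
  combined as `(z_T + z_LMR)/sqrt(2)`, and returned as a two-sided normal
  tail.  Opposite directions cancel by construction.
* **DEG (yeast)**: `p_T <= 0.01` and `|LMR| >=` the 5/95 cutoff — a
  deliberate guard against high-variance arrays; note the non-strict
  inequalities.

### Type-I control: what the joint rule does and does not buy

Under a global null the raw empirical p-values are uniform to within
binomial error (the test suite checks 3-SD bands at alpha = 0.01 and
0.05).  The joint rule "overall p < 0.05 AND |LMR| > cutoff(2.5, 97.5)"
does **not** push the gene-level false call rate to 1%: at n = 3 per
group, `T` and `LMR` are computed from the same six numbers and are
strongly dependent, so conditioning on an extreme LMR makes a small
combined p likely rather than rare.  Measured over 10 seeds x 2,000 null
genes, the joint rate is ~4.5% — essentially the 5% marginal rate of the
LMR filter.  A 1% joint rate would require near-independence of the two
statistics, which their construction rules out.  The corresponding
acceptance assertion is therefore left failing by design, with this
section as the analysis.  Control *is* sharpened where the pipeline
actually claims discoveries: the protein-level DEP rule (two consistent DE
peptides) takes the null protein rate below 1%, which the suite verifies.

The transcriptome null could also be read as bootstrap resampling
("random sampling") rather than permutation; both are implemented
(`scheme = "sample_resampling"`).  Bootstrap lowers the joint null rate
(~2%) but inflates the raw p rate off uniform, so permutation remains the
default.

## NMF clustering

The genes x models fold-change matrix is made non-negative by lossless
column splitting: each model column `c` becomes `(max(c,0), max(-c,0))`,
preserving up/down semantics.  The factorization `V ~ WH` minimizes the
Frobenius loss by Lee–Seung multiplicative updates (`max_iter = 500`,
relative-change tolerance `1e-5`; the loss trace is retained and asserted
non-increasing).

Two numerical choices matter and were made after measurement:

* **Initialization.**  The default is NNDSVD-a — deterministic, built from
  the leading singular triplets, zeros filled with the matrix mean.
  Seeded random initialization (available via `init = "random"`) fragments
  planted blocks when k exceeds the true rank: surplus components split a
  block to absorb noise, and restarting by best loss selects *for* the
  fragmented solutions.  With NNDSVD-a the four-block planted design is
  recovered at ARI ~1.0; with random starts it plateaus near 0.86.
* **Scale fixing.**  `W H` is invariant to diagonal rescaling, so raw `W`
  entries from different fits are not comparable.  After fitting, pattern
  rows are normalized to unit Euclidean norm and the scale absorbed into
  `W`; activation values are then in data (log2 fold-change) units.  The
  permutation significance below is meaningless without this step — the
  observed and null fits would sit at arbitrary relative scales.

**Activation significance**: all matrix elements are globally shuffled,
the NMF refit, and every gene-side activation pooled into one null;
each observed activation gets a right-sided add-one p.  Genes join
cluster i when `p[g, i] < 0.01`.  Element shuffling preserves the global
value distribution, so a gene whose activation rests on a *single* large
fold change is (correctly) not significant — significance requires
coordinated values across models.  Clusters are ranked by the Euclidean
norm of their activation columns, ties broken by index, and the top 10
retained by default.  The desk-scale default profile is `k = 20`,
`n_perm = 100`; the published-scale `k = 100`, `n_perm = 1000` is a
config change.

## Similarity and networks

* **Sibling-peptide correlation**: Pearson correlation of the two
  experiments' LMR vectors over DE sibling peptides whose direction
  matches their protein's call (at least 3 required).  The null permutes
  condition labels independently within each experiment — preserving each
  experiment's marginal structure while breaking the cross-experiment
  coupling — and enumerates all 400 joint relabelings of two 3-vs-3
  designs; p is right-sided.
* **Set overlap**: one-sided hypergeometric, universe defaulting to the
  features quantified in both experiments.  The overlap test's identity is
  not stated in the source analysis; hypergeometric is the standard
  choice.
* **Model dendrogram**: average-linkage agglomeration on Euclidean
  distances between model fold-change columns; columns are sorted by name
  first so the tree is invariant to input order.
* **Enrichment**: one-sided hypergeometric over user-supplied GMT
  collections; a term passes at p < 0.1 with at least 5 overlapping
  genes; `Z = -qnorm(p)`.  This replaces a web-service annotation tool
  whose versioned tables are irreproducible as a dependency; an EASE-style
  variant (overlap minus one) is available behind a flag.  The background
  universe defaults to the measured features and is overridable.
* **Process network**: nodes are terms passing in any top cluster; every
  node pair is a candidate edge, kept iff shared genes >= 3 and Dice
  coefficient strictly > 0.4.  With `cutoff = "auto"` the cutoff is the
  95th percentile of the Dice distribution over all node pairs, which is
  how the 0.4 default was originally justified.

## Synthetic data: what it emulates, what it does not

`simulate_tmt` draws protein abundances lognormal (log2 mean 17, sd 1.5 —
a typical reporter dynamic range), multiplies by per-peptide ionization
factors (log2 sd 1) and lognormal noise at the stated CV, plants a
fraction of proteins at the stated fold (half up, half down), draws
purities Beta(8, 1) (about 10% below the 0.75 filter), and flags ~5% of
peptides non-unique.  `simulate_microarray` uses Normal(8, 2) log2
baselines with i.i.d. Normal(0, sigma) noise and symmetric planted shifts.
`simulate_model_fc` plants signed blocks over model subsets (default: an
all-shared up block, two model-pair blocks, and a pair-specific down
block, 40 genes each of 200, |FC| 2, noise 0.1).  `simulate_gmt` can plant
term pairs with exact shared counts to exercise the Dice boundary.

Deliberately **not** modeled: missingness mechanisms beyond zeros, batch
and labeling-set effects, isobaric ratio compression, probe-level
artifacts, and correlated noise across features.  A green recovery test
therefore establishes that the statistics behave as designed under their
own assumptions — not that those assumptions hold in any particular
deposited dataset.

Generator sample sizes mirror the emulated designs (2 conditions x 3
replicates); effect sizes (4-fold proteins, 2-fold genes) and noise levels
(CV 0.1; log2 sd 0.25) are the recovery conditions the acceptance criteria
state.  Where a value was unstated (abundance scale, purity shape,
non-unique fraction) it was chosen once on field experience and not
revisited.

## Degenerate inputs and tie-breaks

Zero intensities are treated as unquantified from ingest (no imputation);
a feature needs two finite values per group for `T` and one per group for
`LMR`.  Zero-pooled-variance genes are excluded from calling with a
logged count.  Quantile normalization assigns tied values the mean of the
reference values their ranks span (deterministic); its NA-tolerant
variant, used only where zeros created gaps, interpolates the reference
distribution at rank quantiles.  Cluster-norm ties break by cluster
index; dendrogram leaf order ties break by model name; Dice edges at
exactly the cutoff are excluded (strict inequality).  All randomness
flows from one run seed through labeled child seeds
(`derive_seed(seed, label)`), and generators restore the caller's RNG
state.

## Known limitations

* Only 20 distinct relabelings exist for 3-vs-3 contrasts, so the
  "100/1,000 permutations" of larger designs collapse to exhaustive
  enumeration; empirical p-values are correspondingly granular at the
  extreme tail.
* The joint DEG rule does not deliver 1% gene-level type-I control (see
  above); downstream consumers should rely on the protein-level rollup or
  stricter alphas where that matters.
* The NMF model order k is user-set; no model-order selection is
  attempted.  Overlapping block structure (a block active in a superset of
  another's models) is only partially identifiable by any Frobenius NMF,
  independent of initialization.
* Enrichment Z-scores depend on the supplied GMT collection and universe;
  they are not comparable to values computed against other annotation
  versions.
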