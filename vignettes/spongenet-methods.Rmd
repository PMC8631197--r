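---
title: "Inferring competing-endogenous-RNA networks with spongenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring competing-endogenous-RNA networks with spongenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongenet)
library(dplyr)
```

## The problem

Long non-coding RNAs and circular RNAs can act as molecular sponges: a
transcript carrying several miRNA response elements (MREs) sequesters those
miRNAs and thereby de-represses the mRNAs they would otherwise silence.
Whole-transcriptome experiments that profile mRNA, lncRNA, circRNA and
miRNA in the same two-condition design — for instance a disease model with
and without a treatment — allow such competing-endogenous-RNA (ceRNA)
relationships to be inferred from three signals jointly: shared predicted
binding sites, strong negative miRNA–target co-expression, and strong
positive sponge–mRNA co-expression.

spongenet implements that inference end to end: per-class normalization,
negative-binomial differential expression, canonical seed-site scanning,
correlation filtering, a hypergeometric sponge test, network assembly for
both sponge classes, hub-gene intersection, and over-representation / GSEA
enrichment. A synthetic-data generator with planted sponge triplets gives
every stage a ground truth, so the whole pipeline is testable without any
external download.

## The statistical model, stage by stage

### Normalization

Each RNA class keeps its conventional reporting unit: FPKM for mRNA and
lncRNA fragment counts, TPM (reads per million; transcript length taken as
1) for miRNA, and SRPBM — back-splice-junction reads per billion mapped
reads — for circRNA, whose circular structure has no meaningful linear
length.

All *testing* and *correlation*, however, run on median-of-ratios
normalized counts with a single factor per sample estimated from the
pooled mRNA+lncRNA compartments. Two reasons. First, within-sample totals
(TPM, FPKM denominators) are compositional: a handful of strongly
regulated features shifts every other feature's normalized value, which in
our experiments distorted miRNA–target correlations by enough to flip
filter decisions. Second, the small classes (miRNA, circRNA) can have a
large fraction of perturbed features in a strong contrast, in which case a
per-class median-of-ratios is itself biased; the deep mRNA+lncRNA
compartments give a stable depth estimate that applies to all classes of
the same libraries. `size_factors()` itself implements the classic
per-matrix median-of-ratios (features positive in every sample) and
agrees with DESeq2's estimator, which the test suite checks.

### Differential expression

`nb_wald_test()` models counts as negative binomial with variance
$\mu + \alpha\mu^2$. Per feature it computes size-factor-normalized group
means, a log2 fold change with a pseudocount of 0.5 (stability at zero), a
method-of-moments dispersion estimate, a delta-method standard error, and
a Wald statistic referred to the standard normal. Two numerical choices
matter:

* **Dispersion shrinkage.** The per-feature moment estimator is extremely
  noisy at realistic replicate numbers. It is approximately unbiased in
  the mean but not the median, so the estimate is shrunk toward the
  *across-feature mean* on the natural scale (weight `shrink = 0.7`).
  Under null simulations (5 vs 5, $\alpha = 0.1$) this keeps the fraction
  of $p < 0.05$ near nominal, which the acceptance suite verifies.
* **Two cutoff conventions.** Both common DE rules are supported:
  $|\log_2 FC| \ge 1$ with adjusted $p < 0.05$ (the default) and the
  looser adjusted $p < 0.1$ variant; `call_de()` exposes both through
  `lfc_cut` / `padj_cut`, and the looser rule always calls a superset of
  the stricter one.

p-values are adjusted with Benjamini–Hochberg (`bh_adjust()`, a thin
validated wrapper over the standard step-up).

### MRE scanning

`seed_patterns()` builds the four canonical seed classes from miRNA
nucleotides 2–7/2–8 plus the A1 anchor; `scan_sites()` reports every 6mer
anchor once, at its strongest class, with 0-based half-open coordinates on
the target sense strand. DNA input is accepted and read as RNA. No
3'-supplementary pairing, conservation or context scores are computed —
with no parameterization to reproduce, the canonical seed hierarchy plus
an optional duplex alignment score is the defensible core. The optional
score (`duplex_score()`) is a Smith–Waterman local alignment with G:U
wobble (+1) and affine gaps (match +5, mismatch −3, open −8, extend −2),
computed on a window ending at each site; it is off by default because no
standard cutoff exists. The default evidence rule for a miRNA–target pair
is best class at least 7mer-A1.

### Correlation filters and the sponge test

Following standard ceRNA practice, Pearson correlations are computed
across the pooled samples of both groups on $\log_2(\text{normalized
count} + 1)$. Pooling deliberately lets the group contrast contribute to
the correlation — that is what makes $|r| > 0.9$ reachable at a dozen
samples — at the cost of conflating group effect with within-group
co-variation; single-group designs should interpret the filters
accordingly. The thresholds are the conventional ones: miRNA–target kept
at $r < -0.9$, sponge–mRNA kept at $r > 0.8$, both with two-sided
$p < 0.05$ from the $t$ transform.

A sponge–mRNA candidate additionally needs at least three *shared*
miRNAs, where shared means surviving the anti-correlation filter against
**both** partners — the stricter of the two possible readings, applied
identically to lncRNA- and circRNA-based networks. Chance sharing is then
scored with an upper-tail hypergeometric test at $p < 0.05$:

$$p = P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, K, n),$$

with $k$ the shared survivor count and — deliberately — $K$, $n$ and $N$
taken from the *binding-evidence* table over DE features ($K$, $n$: miRNAs
targeting each partner; $N$: all DE miRNAs with evidence on any DE
feature). Basing $K$, $n$, $N$ on binding rather than on the
filter-surviving sets has two consequences we consider essential:
tightening any correlation threshold can only shrink $k$, so the network
is monotone in every threshold (a property the tests check on random
fixtures), and the test cannot degenerate to $p = 1$ when only one sponge
candidate exists. The population choice is configurable in spirit: all
counts are returned in the network's `pairs` table, so any other
convention can be recomputed from it.

### Network assembly and summaries

`assemble_network()` emits a typed graph per sponge class: nodes are the
DE sponge/miRNA/mRNA features of accepted candidates annotated with their
regulation direction, and edges carry the three relation types
(miRNA–sponge, miRNA–mRNA, sponge–mRNA) with their correlation statistics
and, for sponge–mRNA edges, the sponge-test p. Edges are deduplicated on
the unordered endpoint pair and type. `network_summary()` reports node
counts by type and direction and edge counts both in total and for
sponge–mRNA edges only, since size conventions differ on which to quote.
`intersect_hub_mrnas()` returns the sorted mRNAs present in both networks,
and `export_network()` writes TSV (lossless round-trip), Cytoscape SIF and
GraphML.

### Enrichment

`ora_test()`/`ora_batch()` run hypergeometric over-representation of a
study list against user-supplied GMT collections — the same kernel as the
sponge test, with BH adjustment. No live ontology or pathway queries are
made: term-to-gene mappings drift across releases, so the GMT is an
explicit input.

GSEA (`gsea_es()`, `gsea_permutation()`, `gsea_batch()`) ranks features by
the signed Wald statistic (deterministic lexicographic tie-break) and
computes the classic running-sum enrichment score: hits add
$|s|^w / \sum_{hits} |s|^w$, misses subtract $1/(N - n_{hits})$, and the
ES is the signed extremum. At weight 0 the |ES| equals the two-sample
Kolmogorov–Smirnov statistic between hit and miss ranks — an identity the
tests exploit as an oracle; weight 1 (the default) matches the reference
implementation in fgsea. Significance uses *gene-label* permutation: the
package consumes ranked tables, not per-sample phenotype matrices, at this
stage, so phenotype permutation is out of reach by design. NES divides the
ES by the mean same-sign null |ES|; the permutation p is one-tailed within
the observed sign with the +1 correction; FDR uses the positive/negative
normalized-score ratio method (across sets in `gsea_batch()`, its
single-set specialization otherwise).

### Bench quantifications

Two small formulas round out the toolkit: the immunohistochemistry H-score
$H = 1\cdot\%\text{weak} + 2\cdot\%\text{moderate} + 3\cdot\%\text{strong}
\in [0, 300]$ (percent inputs by default, proportions behind a flag), and
qPCR relative expression $2^{-\Delta\Delta CT}$ with
$\Delta CT = CT_{target} - CT_{reference}$ per condition and
$\Delta\Delta CT = \Delta CT_{sample} - \Delta CT_{control}$.

## The synthetic-data generator

`simulate_experiment()` draws a two-group, four-class experiment from a
negative-binomial model,

$$\log_2 \mu_{ij} = b_i + \beta_i\,1[j \in \text{treated}]
  + s_i\,\lambda z_{t(i),j} + \epsilon_{ij},$$

with log-uniform baselines $b_i$ over `nb_mean_range`, true log2 fold
changes $\beta_i \in \{0, \pm\delta\}$, and — for planted triplets — a
per-sample latent sponge factor $z_{t,j}$ entering the sponge and mRNA
with $+\lambda$ and the shared miRNAs with $-\lambda$. Key design choices:

* **Study conditions.** Defaults: 6 replicates per group, 400/200/150/150
  features per class, dispersion $\alpha = 0.05$, DE fraction 0.2 per
  class, $\delta = 3$ (8-fold), 30 planted triplets with 3 shared miRNAs
  each, sequences of 500 nt with embedded 8mer sites. Replicate number and
  effect size are typical of small-animal transcriptome designs; the
  dispersion is at the low end, appropriate for inbred animals.
* **Coupling magnitude.** $\lambda$ is the knob that makes planted
  correlations clear the $\pm0.9/0.8$ filters while leaving the Wald test
  its power; too large a $\lambda$ inflates within-group variance and the
  dispersion estimate with it. A sweep over recall put the optimum near
  $\lambda = 1.1$ (log2 units), the frozen default. The latent factor is
  standardized across samples per triplet so a low-spread draw cannot
  silently weaken the planted correlations, and triplet baselines come
  from the top quartile of the mean range to keep shot noise small.
* **Hub mRNAs.** `n_hub_mrnas` mRNAs are planted in one lncRNA- and one
  circRNA-triplet simultaneously; the two triplets share direction and
  latent factor (and the hub couples once), so the hub-intersection stage
  has an exact expected answer.
* **Sequences.** miRNAs are random 22-mers with globally distinct 6mer
  seeds, constrained so no seed occurs inside another miRNA's 8mer site
  pattern. Targets are uniform-background RNA; planted targets carry one
  recorded site per shared miRNA at fixed spacing. Stray occurrences of
  any planted seed are removed by per-window rejection — each unintended
  occurrence is resampled in place until none remain, which terminates
  where whole-sequence rejection would not (with ~90 planted seeds the
  probability that a fresh 500-nt sequence is clean is astronomically
  small). Scanning the generated sequences therefore recovers exactly the
  recorded sites.
* **Near-noiseless fixtures.** Worked examples that hand-enumerate the
  expected network (for example the one-triplet, 5-node/7-edge star) take
  both noise knobs small: `noise_sd = 0` *and* `nb_dispersion = 0.005`.
  At the default dispersion of 0.05 the NB sampling noise alone leaves a
  percent-level chance per planted pair of falling short of $|r| = 0.9$
  at 12 samples, so "every pair passes" is a limit statement, not a
  default-condition one. Recall under the default conditions is the
  realistic benchmark: about 0.97 of 150 planted triplets over five
  seeds, with no sponge–mRNA edges among non-planted, non-DE features.

What the generator does **not** emulate: read-level sequencing (no FASTQ,
no alignment), isoform structure, GC or length biases, between-library
depth variation, correlated baseline programs among non-planted genes, and
partially occupied or non-canonical miRNA sites. Passing tests therefore
show the *inference machinery* is correct under its own model, not that
the thresholds are optimal for any particular real dataset.

## The orchestrator

`run_pipeline()` executes simulate (or load) → normalize → DE per class →
seed-site scan of DE miRNAs against DE targets → both networks → hub
intersection → ORA and GSEA, logging one line per stage to stderr. All
randomness is governed by two seeds (the generator's and the pipeline's,
both in the config), so a fixed configuration reproduces the result
bundle byte for byte — including the permutation stages — and the written
manifest contains a hash over the config and all output checksums. Problem
sizes in the shipped tests and the acceptance script (hundreds of features,
a dozen samples, hundreds of permutations) were chosen so the full suite
runs in minutes on a laptop while leaving every statistical check
well-powered.

```{r example, eval = FALSE}
cfg <- pipeline_config(sim = sim_config(rng_seed = 1), rng_seed = 1)
bundle <- run_pipeline(cfg)
glance(bundle$networks$lncRNA)
bundle$hub_mrnas
autoplot(bundle$networks$lncRNA)
```

## Known limitations

* Pooled-sample correlations conflate the group effect with co-variation;
  the filters are only as meaningful as that convention.
* The hypergeometric population is one of several defensible choices; all
  counts are exported so alternatives can be recomputed.
* Seed matching is canonical-only; real MRE prediction tools add pairing
  energy, conservation and context features that change the candidate set.
* Gene-label permutation in GSEA ignores inter-gene correlation and is
  known to be liberal on real co-expressed sets; with hundreds of features
  and user-supplied sets it is the reproducible choice available here.
* The NB dispersion estimator is deliberately simple (moments plus
  mean-shrinkage); datasets with strong mean-dispersion trends deserve a
  dedicated DE package.
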