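---
title: "Signature-reversal screening with rank-KS enrichment scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-reversal screening with rank-KS enrichment scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonescreen)
```

## The screening problem

Connectivity-map style drug repurposing asks: given a transcriptional
signature of a biological state we want to undo — here, the genes that
separate stemness-rich neonatal bone tissue from adult tissue, with bone
marrow mesenchymal stem cells (BMMSCs) as the biological context — which
compounds in a library are predicted to push expression in the *opposite*
direction? Each compound is summarised by a change in transcriptional
profile (CTP): a ranking of a fixed gene universe from most upregulated
(rank 1) to most downregulated (rank *n*) under treatment. Such rankings
typically come from an upstream predictor trained on perturbation data;
`bonescreen` treats that predictor as a black box and works entirely on its
rank output, providing a simulator in its place so the scoring machinery
can be benchmarked against planted ground truth.

## The model and its statistics

**Signature extraction.** For a genes × samples matrix with two conditions
(reference and non-reference, at least two replicates each), each gene gets
a linear fold change (ratio of group means, non-reference over reference)
and a two-sided pooled-variance Student's *t* P value with
$n_1 + n_2 - 2$ degrees of freedom. A gene is `up` when FC > 2 and
P < 0.05, `down` when FC < 1/2 and P < 0.05 (strict inequalities; both
thresholds are arguments). The up- and down-gene sets form the query
signature. Design notes:

* *Pooled t, not Welch*: the equal-variance form is the conventional
  "Student's t-test" for small balanced designs; with 3 vs 3 replicates a
  Welch correction has almost no degrees of freedom to estimate.
* *Raw P by default*: the printed fold-change + P rule of this kind of
  screen is a per-gene filter, not an inference; BH adjustment is available
  via `adjust = "BH"`.
* *Degenerate variance*: a pooled variance of exactly zero (possible in
  noise-free simulations) yields P = 1 when the means agree and the
  smallest positive double, with a warning, when they differ.
* *Fold change on linear means*: no pseudocount is added; a reference mean
  of zero gives FC = ∞ and the direction is then decided by P alone. Units
  (counts, FPKM, TPM) are the caller's responsibility.

**Enrichment score.** For a query set with $t$ members found in a profile
over $n$ genes, let $V(j)$ be the ascending-sorted ranks of the members.
The two Kolmogorov–Smirnov deviations between the set's empirical rank
distribution and the uniform distribution are

$$a = \max_{j=1..t}\left(\frac{j}{t} - \frac{V(j)}{n}\right),
\qquad
b = \max_{j=1..t}\left(\frac{V(j)}{n} - \frac{j-1}{t}\right),$$

and the signed enrichment score is $ES = a$ if $a > b$, $-b$ if $b > a$,
and 0 on an exact tie (a symmetric rule that avoids sign flapping). This is
the classical *unweighted* two-sided rank-KS statistic used by
connectivity-map scoring: positive when the set crowds the top of the
profile, negative at the bottom, always in $[-1, 1]$. We deliberately do
not use GSEA-style weighting: the inputs are pure ranks, with no magnitude
to weight by. Query genes absent from the profile's universe are dropped
with a warning and $t$ is the post-intersection count, mirroring screens
where signatures from a whole genome are scored against a fixed predicted
universe.

Useful exact identities (all covered by tests): a single member at rank 1
gives $ES = 1 - 1/n$; at rank $n$, $ES = -1$; the full universe gives
$ES = -1/n$; and reversing a profile (rank $r \mapsto n+1-r$) maps the
deviation pair $(a, b)$ to $(b - 1/n,\; a + 1/n)$.

**Bone score and ranking.** With $a = ES_{\text{up}}$ and
$b = ES_{\text{down}}$ per compound, the default *signed* bone score is
$a - b$: maximal for a compound that upregulates the up-set and
downregulates the down-set, i.e. reverses the signature. The *absolute*
mode ranks by $|a - b|$ instead; it finds strong signature *interactions*
of either sign, so signature mimickers surface alongside reversers — the
mode contrast is itself informative and both numbers are always reported.
An `intersect` option selects only compounds in the top *k* of both
orderings. Ties break by compound identifier, so rankings are reproducible
and invariant to library column order. The default selection size `k = 10`
matches a typical shortlist taken into experimental validation. A `flip`
flag swaps the two query sets for the opposite orientation convention.

## What the simulator emulates — and what it does not

`simulate_expression()` draws per-gene baselines on the log2 scale from
$N(6, 2^2)$, adds $\pm\log_2(\text{FC})$ to the non-reference group means
of planted genes, adds $N(0, \sigma^2)$ noise per observation on the log2
scale, and exponentiates. This keeps every value positive and makes the
planted linear fold change exact in expectation (exactly FC at
$\sigma = 0$). Defaults — 3 replicates per group, 4-fold planted effects,
$\sigma = 0.25$ — emulate a small bulk RNA-seq contrast with strong
age-dependent effects. The log-normal model deliberately omits
count-level sampling noise, mean–variance coupling, library-size
differences and batch structure; passing benchmarks therefore demonstrate
the correctness of the scoring machinery on clean planted signal, not DEG
performance on real counts (for which dedicated count-model tools exist).

`simulate_ctp_library()` gives null compounds independent uniform random
permutations. A planted reverser forces $\lceil s\cdot|up|\rceil$ up-set
genes (a random subset when $s < 1$) onto the top-most ranks and
$\lceil s\cdot|down|\rceil$ down-set genes onto the bottom-most;
mimickers do the mirror image. Forcing works by displacement — the
remaining genes are permuted over the remaining ranks — so each profile
stays a valid permutation regardless of construction order. The strength
knob $s \in [0,1]$ moves planted compounds continuously from null
($s = 0$, labelled but signal-free) to fully forced ($s = 1$). Default
dimensions are 12,328 genes × 961 compounds, a realistic
predicted-universe × FDA-library screen; tests use scaled-down universes
(typically 1,000 × 100) because the statistic's behaviour does not depend
on scale, and the full dimension is exercised once as a determinism and
throughput check. Real CTP libraries are correlated across compounds with
shared mechanisms; the simulator's independent nulls make the benchmark an
idealisation.

## Calibration and benchmarks the package computes

* `permutation_null()` draws bone scores of random disjoint up/down sets
  of fixed sizes against a fixed random profile and returns empirical
  order-statistic quantiles (type-1, so `quantile(x, 0)`/`quantile(x, 1)`
  are the extreme draws) — a cutoff calibration aid, not a significance
  claim about any real screen.
* `recovery_rate()` is the planted-reverser recall in the top *k*. Under
  the packaged study conditions (1,000 genes, 100 compounds, 5 reversers
  at strength 0.8, signed mode, k = 10) recovery is 1.0 in ≥ 95 of 100
  seeds, while at strength 0 it matches the uniform expectation
  $k/m = 0.1$; with 5 mimickers instead, absolute mode places all five in
  the top 10 and signed mode pushes all five into the bottom half in
  ≥ 95% of seeds. These are exactly the checks `tests/testthat/` and
  `scripts/acceptance.R` rerun.

## Numerical and interface choices

* Rank transforms sort descending with ascending-identifier tie-breaks in
  byte (C-locale radix) order, so results do not depend on the session
  locale.
* All file formats are plain text: TSV matrices with explicit headers, GMT
  gene sets, CSV reports. GMT lines need at least three fields; an empty
  extracted signature is written as name + description only and is
  rejected (by design) when read back for scoring, since scoring empty
  sets is undefined.
* `ctp_cli()` wraps each stage as a subcommand
  (`simulate-expression`, `simulate-library`, `signature`, `score`,
  `null`, `evaluate`); every error path prints a one-line diagnostic to
  stderr and exits nonzero without touching result files, and every source
  of randomness is governed by an explicit `--seed`, making full chains
  byte-reproducible.

## Known limitations

The ES formula interpretation (two-sided maximum-deviation KS) and the
signed bone score are documented conventions of this package; screens
built on one-sided statistics or other score combinations will rank
borderline compounds differently. The expression model is log-normal, not
count-based. No dose/time structure, compound chemistry, or
multiple-library batch effects are modelled. The permutation null assumes
exchangeable gene labels, which real co-expression violates.
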