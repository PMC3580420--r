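---
title: "Network enrichment analysis for multi-omics data: models and methods"
author: "neamix maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network enrichment analysis for multi-omics data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neamix)
```

## The problem

A sequenced cancer genome yields thousands of altered genes — point-mutated,
copy-number amplified or lost, allelically imbalanced — of which the
overwhelming majority are passengers. Overlap-based gene set enrichment
(GSEA) can only flag an altered gene set (AGS) if it *shares members* with a
known pathway, which fails precisely in the common situation where each
tumour damages a pathway through different genes, or through genes adjacent
to the pathway rather than inside it. Network enrichment analysis (NEA)
replaces shared membership with shared *connectivity*: an AGS is related to
a functional gene set (FGS) if the gene network contains more links between
them than degree-preserving chance allows.

`neamix` implements this statistic together with the upstream genomic
filters that produce credible altered gene sets from copy-number, RNA and
protein data, and a synthetic-data layer that plants known ground truth so
the whole workflow can be exercised and falsified without access to any
proprietary network or cell-line data.

## The enrichment statistic

For gene sets $i$ and $j$, let $n_{ij}$ be the number of links between them
in the network. Two link statistics are supported:

* **direct** — network edges with one endpoint in each set. An edge inside
  the intersection of the two sets counts once.
* **indirect** — two-step paths $a\!-\!x\!-\!f$ with $a \in i$, $f \in j$,
  $a \neq f$, through any intermediate $x$ that is not an endpoint. Each
  unordered path counts once, so a single gene pair can contribute many
  links (one per shared neighbour). Whether $a\!-\!f$ are also directly
  linked is irrelevant. The indirect statistic exists because any inferred
  network is incomplete: genes whose coupling is missed as an edge are often
  still visibly coupled through common neighbours.

The null distribution of $n_{ij}$ depends strongly on the degrees of the
member genes — biological networks are approximately scale-free — so
enrichment is judged against *degree-preserving* network randomization:

$$z = \frac{n_{ij} - \hat n_{ij}}{\sigma_{ij}}$$

where $\hat n_{ij}$ and $\sigma_{ij}$ are the sample mean and standard
deviation (denominator $n-1$) of the link count over `n_perm` randomized
networks (default 50, which is sufficient for moment estimation at this
granularity). Under the null the z-scores are approximately standard normal,
and one-sided upper-tail P-values are reported. Depletion is visible as
negative $z$ but is deliberately not converted into a small P-value: the
analysis asks for enrichment. When the null ensemble is degenerate
($\sigma_{ij} = 0$, e.g. sets of isolated genes, or rigid graphs such as
complete graphs) and the observation equals the null mean, $z$ is reported
as undefined with $p = 1$.

## Randomization: why rejected swaps consume the budget

Randomized networks are produced by double-edge swaps — replace edges
$a\!-\!b$, $c\!-\!d$ by $a\!-\!c$, $b\!-\!d$ (or $a\!-\!d$, $b\!-\!c$) —
which preserve every node's degree and the edge total. Each permutation
starts from the *original* network (ensemble members are independent, not
chained) and performs `ceiling(swap_factor * |E|)` proposal steps
(`swap_factor = 10` by default, a standard mixing allowance).

A design point that matters numerically: a proposal that would create a
self-loop or a duplicate edge is rejected, and the rejection **consumes a
step**. The seemingly innocuous alternative — retry until some swap
succeeds — produces a Markov chain that always moves, whose stationary
distribution weights each graph by its number of valid swaps. On small
graphs this bias is easily measurable: against exhaustive enumeration of all
simple graphs with the same degree sequence, the retry chain mis-estimates
null standard deviations by tens of Monte-Carlo standard errors. With
rejections counted as (lazy) steps the proposal distribution is
state-independent and symmetric, the stationary law is exactly uniform over
the degree-sequence ensemble, and the estimated moments agree with
enumeration within Monte-Carlo error (this is verified in the acceptance
suite on twenty 6–8-node graphs for both statistics). Graphs admitting no
valid swap at all, such as stars, are returned unchanged with a warning.

## False discovery rates

Two empirical FDR estimates are provided, both exploiting the fact that no
*depletion* findings are expected in this analysis:

* **left tail** (default): $\mathrm{FDR}(z_0) = \#\{z \le -z_0\} / \#\{z
  \ge z_0\}$ over the result list, clipped to $[0,1]$. The depletion side of
  the z distribution estimates how much of the enrichment side is noise.
* **random sets**: the test is re-run on random AGS of the same size and
  binned degree profile (bins at powers of two; degree-0 genes form their
  own bin; underfilled bins widen to neighbouring bins).
  $\mathrm{FDR}(z_0)$ is the mean per-randomization count of random-set
  z-scores $\ge z_0$ divided by the observed count $\ge z_0$.

P-value lists from the overlap comparator are adjusted with the
Benjamini-Hochberg step-up, implemented directly and tested against both a
hand computation and `stats::p.adjust`.

## The genomic filters

The integrative workflow asks which of the thousands of copy-number-altered
(CNA) genes actually matter, using two orthogonal filters:

1. **Dosage filter.** A gene whose copy number drives its biology should
   show expression (and, attenuated, protein) levels that track copy number
   across samples. Per gene, Spearman correlations between copy number and
   RPKM, and copy number and protein intensity, are computed across cell
   lines; the mean of the available terms must exceed `corr_threshold`
   (default 0.8), and the gene must be expressed at all (`max RPKM >=
   rpkm_min`, default 1). With only three lines the per-gene Spearman is
   extremely coarse (values in $\{-1, -0.5, 0.5, 1\}$ plus ties), which is
   why the workflow never relies on this filter alone; a permutation control
   (`permutation_log_ratio()`) quantifies, per correlation threshold, the
   log-ratio of observed to permuted exceedance counts (pseudo-count 0.5 on
   both sides; threshold grid 0–1 in steps of 0.1). Genes with tied copy
   numbers have an undefined correlation and are excluded rather than
   scored zero. Whether the 0.8 threshold applies to the transcription term
   only or to the mean with protein is genuinely ambiguous in the source
   material; both readings are supported (`use_protein`), the default being
   the mean.
2. **Network context filter.** Each surviving candidate is individually
   tested for enriched connectivity to the sample's damaging-SNV gene set
   (the far more sharply delineated alteration class, used as reference);
   genes with $z >$ `z_threshold` (default 1.96, the conventional FDR < 0.1
   operating point) are kept. The default statistic is **indirect**: a
   single gene contributes only a handful of direct edges, so the direct
   count is a small discrete number for which the normal approximation at
   1.96 is poorly calibrated, while the two-step count pools over all shared
   neighbours and behaves far better. (`direct` and `both` remain
   available.) All candidates share one ensemble of permuted networks,
   which is what makes testing hundreds of genes at 50 permutations cheap.

The damaging-SNV set itself is assembled by dropping common polymorphisms,
dropping variants below a DNA allele-fraction floor (default 0.2 — an
explicit *approximation* of an unpublished subclonal-heterogeneity rule),
and keeping variants annotated as protein-damaging by an external predictor
(the prediction itself is out of scope; flags are consumed as annotation).

Allelic imbalance is called per variant: heterozygous at DNA (allele
fraction in `[0.3, 0.7]`), essentially monoallelic in RNA (allele fraction
$\ge 0.95$ or $\le 0.05$), both depths $\ge 10$. These bands are
conventional choices — the source material leaves the exact values to
supplementary detail — and fully configurable. A gene is AI if at least one
variant supports it.

`build_ags()` packages the three alteration classes plus their union as the
altered gene sets for the set-vs-set stage, which runs NEA for every
AGS–FGS pair (optionally AGS–AGS pairs as well), fills FDRs, applies the
default significance filter $p < 0.05$, FDR $< 0.10$, and cross-tabulates
agreement with the hypergeometric comparator.

## What the synthetic generators emulate — and what they do not

`simulate_network()` plants densely connected modules (default: one module
of 40 genes at within-module edge probability 0.25) in an Erdős–Rényi
background (500 genes, density 0.01). This reproduces the one topological
property NEA relies on — functionally related genes cluster — but not
degree power-laws, hierarchical modularity, or edge-confidence structure of
inferred networks. A green planted-module test therefore establishes that
the statistic detects concentrated connectivity against a degree-fair null;
it does not certify performance on a real 900k-edge integrated network.

`simulate_omics()` draws per-line copy numbers (mostly diploid, gains and
losses at comparable rates by default; per-line gain/loss presets emulating
heavily rearranged genomes are available via `cn_profile_preset()`), and
generates `log RPKM = baseline + cn_effect * log(CN/2) + noise` with
log-normal baseline `exp(N(1.5, 1))`, `protein = attenuation * logexpr +
protein noise`. Copy number 0 maps to an effective 0.5 copies before the
log (residual transcription rather than minus infinity). The default
protein noise is calibrated analytically: with attenuation $\alpha = 0.7$,
expression variance $\approx 1.39$ at the defaults, the Pearson correlation
$\alpha\,\mathrm{sd}(e)/\sqrt{\alpha^2\mathrm{var}(e) + s_p^2}$ hits
$\approx 0.59$ (Spearman $\approx 0.58$) at $s_p = 1.1$ — the middle of the
0.55–0.61 band reported for deep transcriptome/proteome comparisons of
cancer cell lines. The acceptance suite asserts the band on generated data;
it does not, and cannot, assert anything about real proteomes.

`simulate_variants()` plants heterozygous DNA sites (binomial allele
fraction 0.5) whose RNA is either balanced (0.5) or monoallelic (0.98/0.02)
for planted AI genes. Planted AI and damaging genes are guaranteed at least
one sequenced site — a planted truth that is never observed would merely
measure the site-assignment lottery.

`simulate_bundle()` ties everything together on one 500-gene universe for
the end-to-end test: a 50-gene module containing 15 SNV-reference genes, 20
planted drivers (copy-number-responsive, `cn_effect = 2`, `noise_sd = 0.3`,
attenuation 0.8, protein noise 0.4, copy-number profiles drawn from
distinct states in $\{1, 2, 4, 8\}$) and 15 untouched module genes used as
a functional set that is *connected to* but *disjoint from* every altered
set — the configuration where NEA can see what overlap statistics cannot.
Ten equally clean dosage-responsive decoys live outside the module to probe
the context filter. The driver cohort size is a power decision: at the
default thresholds the workflow has an irreducible false-positive floor of
roughly ten genes on this topology (dominated by genes genuinely one
network hop from the module, plus occasional perfect three-point rank
agreements among the ~400 noise candidates), so recovery is planted well
above that floor; a cohort at or below the floor would test fixture shot
noise, not the method. Drivers are planted with a strong, clean dosage
effect deliberately: the end-to-end criterion tests the recovery machinery,
not borderline calling.

## Numerical and design choices

* Gene identity is the raw symbol string, case-sensitive, no alias
  resolution; determinism beats coverage here.
* Merged networks union nodes, edges and per-edge evidence tags; scores
  combine by maximum and are retained but unused by the statistics (the
  sources threshold confidence upstream).
* All randomness flows through R's RNG; permutation $k$ of a null ensemble
  is seeded `seed + k - 1`, so a 1×1 `nea_matrix()` call reproduces
  `nea_test()` exactly, and every pipeline run is byte-identical under a
  fixed master seed.
* One-sided upper-tail P-values throughout; the z↔P correspondences quoted
  in the source material are not mutually consistent under either one- or
  two-sided conventions, so the convention is fixed here and documented.
  (Similarly, the source's count of "334 = 2 × (57+51+54)" single-gene
  tests is arithmetically 324; noted, not resolvable.)
* FDR clipping to $[0,1]$; zero-denominator FDRs are 0 when nothing is
  observed at or above the threshold.
* The intersection convention (genes in both AGS and FGS stay in both; an
  edge inside the intersection counts once; an indirect path never has
  identical endpoints) follows the literal reading of "links between any
  genes of $i$ and any genes of $j$".

## Known limitations

* The per-gene dosage filter at three samples has very low resolution; its
  false positives are controlled only in combination with the network
  context filter, exactly as in the source workflow.
* The left-tail FDR is a coarse estimator when the result list is short.
* The random-set FDR's degree-matched sampling can draw heavily from a
  planted module on *small* networks, where high-degree bins and module
  membership coincide; on realistically sized networks the bins decouple.
* Single-gene direct-mode z-scores remain poorly calibrated on sparse
  networks; the package defaults steer around this but expose the raw
  statistic.
* Edge evidence tags and scores are carried but not modelled; confidence-
  weighted enrichment is out of scope.

## Relation to the acceptance suite

Every quantitative claim above is checked in
`tests/testthat/test-acceptance.R`: exact degree preservation over 1,000
rewiring calls; null moments vs exhaustive degree-sequence enumeration on
twenty small graphs (both statistics, 3 Monte-Carlo SEs); null z-score
normality on $G(200, 0.05)$ (mean, sd, Kolmogorov–Smirnov); planted-module
recovery and NEA-vs-GSEA sensitivity over generator seeds 1–20;
hypergeometric exactness against brute-force enumeration for all $N \le
25$; AI-caller sensitivity $\ge 0.9$ at FDR $\le 0.1$ over seeds 1–10; the
calibrated mRNA–protein band; and deterministic end-to-end driver recovery
at Jaccard $\ge 0.5$ on the seed-7 bundle.
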