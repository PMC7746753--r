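---
title: "Matrix-GC: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matrix-GC: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matrixgc)
```

## The problem

Methyl-CpG-binding proteins such as MeCP2 bind DNA with only a weakly
informative sequence motif; what sharpens their genomic distribution is a
strong preference for GC-rich context. A plain position-weight-matrix (PWM)
scan of promoters therefore produces many spurious calls, while GC content
alone ignores the motif entirely. `matrixgc` implements the combined
classifier — called Matrix-GC here — that requires both signals: a gene's
promoter is called *bound* when it contains at least one PWM match at or
above a percent-score threshold whose surrounding sequence window is at or
above a GC-content threshold. Around that classifier the package provides
the apparatus needed to use it responsibly: ROC calibration of the score
threshold against ranked positive and bootstrapped negative control gene
sets, Fisher exact tissue-expression contrasts of bound vs not-bound genes,
a Monte Carlo permutation test of differential-expression enrichment, and a
degree-based permutation null for protein–protein interaction (PPI) network
connectivity with hub calling.

## The classifier

**Promoters.** The promoter of a gene is the `upstream` bases (default
1000 bp) immediately 5' of its transcription start site (TSS), read toward
the TSS. Coordinates are 0-based and half-open internally; gene tables may
declare a 1-based convention with `coord_base = 1`. Minus-strand promoters
are reverse-complemented before scanning so that every promoter reads 5'→3'
relative to its gene; scanning is forward-strand only by default
(`both_strands = TRUE` is available but the biological reading direction is
already fixed by the extraction). Promoters that would overhang a chromosome
end are clipped rather than rejected, with the realized length recorded —
rejection would silently drop genes near contig boundaries.

**PWM and percent score.** A position frequency matrix (counts, 4 × W;
the bundled synthetic example has W = 15) is converted to log2-odds weights
against an explicit background $b$ with an additive pseudocount $c$ shared
across each column in proportion to the background:

$$ w_{b,j} = \log_2 \frac{(n_{b,j} + c\,\pi_b) / (N_j + c)}{\pi_b} $$

with $N_j$ the column total and $\pi$ uniform by default. A window of width
W gets the raw score $S = \sum_j w_{s_j, j}$, reported on a 0–100 scale by
min–max normalisation between the matrix's achievable bounds
$S_{\min} = \sum_j \min_b w_{b,j}$ and $S_{\max} = \sum_j \max_b w_{b,j}$:

$$ \mathrm{percent} = 100\,\frac{S - S_{\min}}{S_{\max} - S_{\min}}. $$

The percent score is invariant to adding a constant to any column, so it
does not depend on the pseudocount or background beyond their effect on the
*shape* of each column. Windows containing any non-ACGT symbol are skipped
(hg19-style promoters contain N runs); skipped windows are counted and
reported as an attribute. Overlapping matches are all retained — gene
classification needs only "at least one", so non-maximal suppression would
change nothing and is not applied.

**GC window.** For each match the GC percent is computed over the match
plus `flank` bp (default 100) on each side — 215 bp for a 15 bp motif when
unclipped. Windows at promoter edges are truncated, not discarded, and GC is
computed over the available bases; N bases are excluded from both numerator
and denominator, since counting them as non-GC would arbitrarily penalise
repetitive-region promoters.

**Decision rule.** With the default configuration
(`matrixgc_config()`: PWM threshold 65, GC threshold 60, upstream 1000,
flank 100), a gene is bound iff *any* match at percent ≥ 65 has window GC
≥ 60. Applying the GC filter to every match rather than only the best-scoring
one is the more permissive of the two readings and the one consistent with
the "at least one passing site" semantics of the output; with
`gc_threshold = 0` the classifier reduces exactly to plain PWM matching.

## Threshold calibration by ROC

The ROC unit is the *gene*, not the window: at threshold $t$ a gene
classifies bound when its best GC-passing match score is at least $t$.
TPR at $t$ is the bound fraction of the positive control genes; FPR is the
mean, over `n_bootstrap` (default 10) without-replacement size-matched draws
from the negative pool, of the bound fraction of each draw — point-wise
averaging of FPR values, not averaging of per-replicate AUCs. Points are
anchored at (0,0) and (1,1), sorted by FPR, and integrated by the trapezoid
rule. The implementation scans each promoter once (at threshold 0) and
summarises it by its best GC-passing score; per-threshold classification is
then a comparison. This is exactly equivalent to re-scanning per threshold
because match sets are nested in $t$ and the GC window does not depend on
$t$; the equivalence is tested against a brute-force per-threshold oracle.
`compare_gc_settings()` re-uses identical bootstrap draws across GC
settings so curves are paired and differ only through the GC filter.

## Statistical procedures

**Tissue contrasts.** For each tissue, genes are cross-tabulated by bound
status and by expression strictly greater than the cutoff (default 0; a
value exactly at the cutoff counts as not expressed). The two-sided Fisher
exact p-value comes from the hypergeometric distribution; the reported odds
ratio is the sample ratio $ad/bc$ ($\infty$ when $bc = 0$ and $ad > 0$).
Raw p-values are reported with no multiplicity correction across tissues or
disorders — callers comparing many tissues should correct downstream.

**Monte Carlo DEG test.** The observed statistic is the percentage of
candidate genes with DE p ≤ α (default 0.05, inclusive); the null is the
same percentage in `n_perm` (default 1000) random gene sets of equal size
drawn without replacement from the DE-table universe. Candidates absent
from the DE table are dropped and the effective size used for the draws.
The empirical p uses the add-one convention
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + N)$, so it is never zero and is
bounded below by $1/(N+1)$; ties count against the candidate set. These
conventions make the test conservative when the statistic is coarse: for
small candidate sets (tens of genes) the percentage takes few values, tie
mass is large, and the null rejection rate at 0.05 falls visibly below
nominal (≈ 0.02 at 50-gene sets in our simulations). At disorder-set sizes
(hundreds of genes against a transcriptome-scale universe) the statistic has
enough support and the rate is close to nominal (≈ 0.036–0.04, still
slightly conservative by construction).

**Term exclusion.** Enrichment terms significant in any random control gene
set are excluded from a disorder's significant terms; the package operates
on the tabular outputs of external enrichment tools and treats term ids as
opaque strings.

## Network connectivity null and hubs

The "connectivity" of a gene set is its mean induced-subgraph degree on the
(undirected, deduplicated, self-loop-free) PPI graph; genes absent from the
graph count with degree 0. The null draws `n_runs` (default 20) random
size-matched sets from the universe and records each run's mean degree, the
extremes, and the mean of means. A disorder set is significantly connected
when its observed mean degree *strictly* exceeds the maximum control-run
mean — an exceedance-of-range rule, not a parametric test. A protein is a
hub when its within-network degree is at least one above the control mean
(`degree ≥ mean + 1`, inclusive — "at least 1 greater" is adopted where the
alternative strict reading would differ only at the boundary). Whether the
control draws come from the whole proteome or the measured universe is the
caller's choice via the `universe` argument; the pipeline defaults to the
graph's own node set.

## What the synthetic generators emulate

`synth_cohort()` builds promoters with known truth: planted exact-consensus
sites (percent score 100, so threshold behaviour is unambiguous; `degrade`
mutates k positions to exercise intermediate scores) embedded in flanks
synthesised to hit a target window GC within ±2 points (bounded retries,
then an error when the site's own composition makes the target infeasible),
over iid background at a target GC. Defaults are the study conditions:
1000 bp promoters, 70% window GC for positive contexts, 40% background GC
(near the genome-wide human average), motif-free negatives.
`synth_expression()` places exactly `round(frac · n)` log-normal expressed
values per tissue and exact zeros elsewhere; `synth_de_table()` mixes
uniform null p-values with an enriched set significant at a stated rate;
`synth_ppi()` is a named Erdős–Rényi graph with an optional planted clique.
All generators are pure functions of their arguments and a seed.

What they do *not* emulate: real promoter base composition (CpG islands,
repeats, N runs at scale), isoform-resolved TSS choice, correlated
expression across tissues, DE p-value dependence structures, and the
degree heterogeneity of real PPI networks. Passing tests therefore
demonstrate the correctness of the algorithms and their calibration under
idealised conditions, not performance on real genomes — the study's
headline numbers on ChIP-seq-ranked controls depend on external data and
are out of scope here.

## Numerical and design choices

* Pseudocount 0.01, uniform background: small enough not to distort
  informative columns, large enough to keep zero-count log-odds finite.
* Degenerate matrices with $S_{\max} = S_{\min}$ score 100 by convention
  (every window is a perfect match of a no-information motif).
* ROC grid: 5 to 100 in steps of 5 (the conventional stratification for
  this procedure); AUC by trapezoid after sorting; negative resampling
  without replacement within each replicate.
* Bootstrap and permutation draws consume a locally scoped RNG
  (`withr::with_seed`) so library calls never disturb the caller's RNG
  state; the pipeline fans a single base seed out to per-stage sub-seeds by
  fixed offsets.
* Duplicate gene names are rejected at input; ties in hub ordering break
  alphabetically so output is stable.
* Edge cases: sequences shorter than the motif scan to an empty result (not
  an error); empty FASTA files read to an empty mapping; all-N GC windows
  are undefined and never pass the filter.

## Problem sizes used by the test suite

The package's tests run cohorts of 10–200 promoters of 400–1000 bp,
ROC curves on 15 positives vs 30 negatives with 10 bootstraps, an
800-table Fisher enumeration sweep, a 500-repetition Monte Carlo
calibration at 200 permutations against a 15 000-gene universe, and network
nulls on graphs of up to 200 nodes — sizes chosen so the whole suite
exercises every code path with exact oracles in about a minute.

## Known limitations

* The classifier is promoter-only; core gene-body scanning is not
  implemented.
* Percent scores are not p-value calibrated; the 65% default is meaningful
  relative to a motif's own score range, not across motifs.
* The Fisher contrast conditions on the bound/not-bound split produced by
  the same pipeline, so it tests association, not causality.
* The connectivity significance rule (exceeding a 20-run range) has a
  granularity of roughly 1/20; it cannot produce p-values below ~0.05 and
  is best read as a screening rule.
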