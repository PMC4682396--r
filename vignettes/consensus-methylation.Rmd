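---
title: "Consensus methylation calling: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus methylation calling: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsmerge)
```

## The consensus model

Bisulfite conversion leaves methylated cytosines as C and turns
unmethylated ones into T, so the methylation level of cytosine $i$ as seen
by mapper $j$ is the unconverted fraction

$$M_{ij} = \frac{N^c_{ij}}{N^c_{ij} + N^t_{ij}},$$

where $N^c$ and $N^t$ count reads observing C and T. `bsmerge` merges the
levels of the $n_i$ mappers covering position $i$ by three convex
combinations:

* **Ave**: $\sum_j M_{ij} / n_i$;
* **wAve**: $\sum_j W_{ij} M_{ij}$ with depth weights
  $W_{ij} = N^d_{ij} / \sum_j N^d_{ij}$;
* **pwAve**: $\sum_j W^p_{ij} M_{ij}$ with
  $W^p_{ij} \propto f(N^d_{ij};\lambda_j)$, $f$ the Poisson probability
  mass function and $\lambda_j$ mapper $j$'s mean read depth over the
  whole reference.

Weights are normalised over the *covering* mappers only. A mapper without
coverage at a position is excluded from all sums rather than contributing
a zero level — this is the only normalisation that keeps every merged
level inside $[\min_j M_{ij}, \max_j M_{ij}]$, and it means a mapper
reporting a genuinely unmethylated site (level 0 at good depth) still
counts as evidence. The literal alternative, counting only mappers with
$M_{ij} > 0$, would silently discard unmethylated calls; it remains
available via `positive_level_only = TRUE` but is not the default.

The intuition behind the two weighted schemes differs. wAve trusts depth:
a level backed by more reads is more reliable, and depth tracks mapping
rate. pwAve is sceptical of *anomalous* depth: a mapper that piles up far
more (or fewer) reads at a position than its genome-wide mean predicts is
likely to be contributing misplaced reads there, and the Poisson mass at
the observed depth down-weights exactly those positions. The Poisson mass
is evaluated in log space and rescaled by the maximum before
normalisation, so large depths cannot underflow; in the fully degenerate
case (every mass zero, e.g. $\lambda = 0$ with positive depth) the
weights fall back to depth weights with a warning.

### Key parameters

| parameter | default | meaning |
|---|---|---|
| `min_mappers` ($k$) | 2 | emit a position only when at least $k$ mappers cover it. $k=1$ keeps everything any mapper saw; $k=3$ maximises agreement but sharply cuts the detected amount at high read error. $k=2$ keeps the detected amount above the strictest single mapper while still averaging away mapper-specific noise. |
| `min_depth` ($d$) | 1 | reads required for a mapper to count as covering. 1 is appropriate for simulated reads with known truth; 5 is the conventional confidence threshold for real WGBS. |
| `lam` ($\lambda_j$) | estimated | mean depth over *all* reference cytosines of the analysed context set, zero-depth positions included (`covered_only = TRUE` averages over covered positions instead). |

Levels are computed on $[0,1]$ throughout; the evaluation reports
d-accuracy and mapping rates on the percent scale.

## What the simulator emulates

Real benchmarking of bisulfite mappers requires a reference genome, a
read simulator and the mapper executables. The package replaces this
stack with a statistically equivalent test bed:

1. **Reference and truth** (`make_reference`): a random A/C/G/T sequence
   tiled into 500-bp blocks; each block gets independent uniform CpG and
   CpH truth levels. A configurable fraction of blocks (default 0.25,
   reflecting the repeat-rich chromosome arm such benchmarks use) are
   near-identical copies of one motif (2% divergence) and stand in for
   interspersed repeats, where mapper behaviour diverges most.
2. **Reads** (`generate_reads`): forward-strand reads with uniform starts
   inside a block, never straddling block boundaries (the reference is
   fed to the generator block by block). Each reference C in a read stays
   C with probability equal to its block's truth for its context,
   otherwise becomes T; sequencing errors then substitute bases uniformly
   (no indels, constant quality — a deliberate simplification of
   quality-curve error models). Defaults are 50 reads of 100 bp or 100
   reads of 50 bp per 500-bp block, i.e. exactly 10x mean coverage.
3. **Mapper emulation** (`emulate_mapper`): each read is independently
   unmapped, correctly placed, or misplaced to a uniformly random wrong
   position. The probabilities respond linearly (clamped to $[0,1]$) to
   the read's realized error fraction, its T fraction, and its block's
   repeat flag. Misplaced reads *deposit* their C/T observations at the
   wrong positions rather than being dropped — this is the mechanism that
   degrades single-mapper accuracy and that the consensus corrects.

The three presets (`preset_profiles()`) encode the published mapper
phenotypes: the wild-card mapper maps the most clean reads but its rate
collapses with read error and its accuracy suffers in T-rich reads and
repeats; the accurate three-letter mapper is T-insensitive but
error-sensitive and loses reads in repeats; the local-alignment
three-letter mapper barely reacts to read error but misplaces T-rich
reads. The preset magnitudes were chosen so the emulated mapping rates and
accuracies across the 0–8% error grid sit in the ranges reported for the
real mappers (rates roughly 0.3–0.8 at 8% error; with these values the
probability that all three mappers place a read correctly at 8% error is
about 0.07, matching the published overlap figure). They are fixed
constants of the package, not fitting targets.

### Truth for scoring

The evaluation truth for a block is the *realized* conversion rate — what
the generator actually wrote into the reads — not the drawn target level,
so generator sampling noise never counts against a mapper. Realized truth
is aggregated as the unweighted mean over covered cytosine positions of
each position's conversion fraction, the same convention used for
detected block levels (`block_detected_levels`); with this pairing a
perfect mapper recovers truth exactly and d-accuracy is exactly 100. The
alternative (pooling all read observations, i.e. depth-weighting
positions) would leave a small irreducible gap between truth and the
position-averaged detected level even for a perfect mapper, conflating
the aggregation convention with mapper error.

Blocks with no covered cytosine of the requested context are excluded
from the d-accuracy mean rather than scored 0: coverage shortfalls are
what d-amount measures, and scoring them 0 would double-count quantity as
quality. CpG and CpH (= CHG ∪ CHH) are always evaluated separately.

## Evaluation and comparison choices

* **d-accuracy** $= 100\,(1 - |\text{generated} - \text{detected}|)$ per
  block, averaged over blocks with a defined detected level.
* **d-amount** = cytosine positions at or above the depth threshold; for
  consensus output, positions passing the $n_i \ge k$ emission rule.
* **Paired Wilcoxon signed-rank** (`wilcoxon_paired`) compares two
  methods' per-block d-accuracies: zero differences dropped, exact null
  for up to 25 non-zero untied pairs, normal approximation with
  continuity correction beyond, `p = 1` with a warning when every
  difference is zero.
* **Repeat-region scoring**: synthetic blocks carry an `is_repeat` flag,
  so the >50%-overlap rule used for interval-annotated real data reduces
  to selecting flagged blocks (`score_calls(..., blocks = )`).
* **Multi-sample comparison**: per-sample consensus levels are binned
  into fixed blocks (10 kbp by default; position 10,000 belongs to block
  1 under 1-based inclusive tiling), distances are $1 - \rho_{Spearman}$
  with average ranks for ties and pairwise-complete blocks per sample
  pair (a complete-blocks mode exists), and trees use average linkage
  (UPGMA) — the linkage convention of methylome dendrograms; single and
  complete linkage are available.

## Numerical and degenerate-input conventions

Coordinates are 1-based and strand-specific everywhere internally;
bedGraph export converts to 0-based half-open on write only. Symmetric
CpG strand merging is off by default (the supported mapper outputs are
strand-specific). Zero-depth rows in inputs are preserved by the readers
and excluded by the integration's depth filter; a missing position is the
absence of a row, never a zero-depth record. BSMAP's fractional
`eff_CT_count` is ignored in favour of the integer `CT_count` so depths
stay integral. Degenerate evaluations (no reads, no mapped reads, zero
variance) raise errors rather than returning NaN.

## Problem sizes

The test suite and the acceptance script run the simulation at desk
scale, chosen to keep binomial noise well below the effects being
measured: references of 100–200 blocks (50–100 kbp), 10x coverage, the
full 2-length × 5-error grid with 3–10 replicates, and 10 seeded
replicates for directional claims (consensus vs single mappers,
variance damping, tissue clustering). At this scale one campaign takes
tens of seconds; the qualitative behaviour (consensus ≥ best single
mapper at high error, d-amount above the strictest mapper, reduced spread
across conditions, tissue-first clustering) is stable across seeds.

## What passing tests do and do not show

The simulator reproduces the *statistical structure* that makes consensus
merging work: partially independent mapper errors, depth that tracks
mapping rate, misplacement that rises with T density and repeats.
It does not model PCR duplicates, adapter contamination, quality-score
profiles, paired-end reads, reverse-strand reads (a both-strand flag
exists but is not exercised by the shipped benchmarks), indels, or the
LINE/SINE distinction (one repeat class). Conclusions about real WGBS
data therefore carry the usual caveat: the consensus improves accuracy
*given* mappers whose errors are partially independent; mappers sharing a
failure mode (e.g. identical treatment of a repeat family) gain less from
merging than the emulator suggests.
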