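---
title: "Overlap enrichment for genomic region sets: model, choices, limits"
author: "lociRank maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlap enrichment for genomic region sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lociRank)
```

# The question the package answers

Many genomics experiments end in a list of genomic intervals — ChIP-seq
peaks, differentially methylated regions, accessible chromatin — rather
than a list of genes. To interpret such a *query set*, we ask which
annotated region sets in a reference database (transcription-factor binding
catalogs, DNase hypersensitive sites, chromatin states, ...) it overlaps
more often than chance would predict. Three ingredients define every
analysis:

* the **query set(s)**: the regions of interest;
* the **universe**: the background regions that could, in principle, have
  been in the query (e.g. all regions covered by the assay);
* the **reference database**: collections of annotated region sets, each a
  BED file on disk.

# The statistical model

For one query $Q$ and one database set $S$, each universe region is
classified by two binary labels — "is in the query" and "overlaps $S$ by at
least `minOverlap` base pairs" — giving the 2×2 table

|                | in query | rest of universe |
|----------------|---------:|-----------------:|
| overlaps $S$   | $a$      | $b$              |
| no overlap     | $c$      | $d$              |

with $a + c = |Q|$ and $a + b + c + d = |U|$. Treating regions as
independent draws, the null distribution of the support $a$ with all
margins fixed is hypergeometric, and we report the one-sided Fisher exact
p-value in the enrichment direction,

$$ p = P(X \ge a), \qquad X \sim
   \mathrm{Hypergeom}(|U|,\; a+b,\; |Q|). $$

Depletion is deliberately not scored: the output is a ranking of
enrichments, and a two-sided test would let strong depletions surface among
the top hits.

Three measures are computed per database set: the p-value, the smoothed
sample log odds ratio
$\log\big((a+0.5)(d+0.5) / ((b+0.5)(c+0.5))\big)$,
and the support $a$ itself. Each is converted to a competition rank
(ties share the smallest applicable rank), and the composite score is the
**worst** of the three ranks (`maxRank`). A set must do well on
significance, effect size *and* absolute overlap to rank highly; this
suppresses hits that are significant only because they are huge (tiny odds
ratio) or have an extreme odds ratio on two overlapping regions.

p-values are corrected by the Benjamini–Hochberg step-up procedure
(`stats::p.adjust`), applied within each query across **all** database
entries of all collections jointly — the most conservative interpretable
default; a per-collection correction would make q-values incomparable
across collections.

## Assumptions, and when they break

* *Independence of regions.* Real regulatory regions cluster; the exact
  test does not know this, so p-values on strongly clustered queries are
  anti-conservative. The ranking (which is what the tool is for) is much
  less sensitive than the absolute p-values.
* *The universe contains the query.* Cell $b$ is computed as (universe
  hits − query hits) and clamped at zero with a warning when the query is
  not a subset of the universe. `checkUniverseAppropriateness()` reports
  query/universe coverage, relative sizes and chromosome-name mismatches
  (exact string matching: `chr1` and `1` are different chromosomes, by
  design, because silent genome-build mismatches are the classic failure
  mode of this analysis).
* *Counting units.* Query regions that miss the universe entirely still
  count in $c$; dropping them would silently bias the test toward
  enrichment. Remapping the query onto universe units is available but
  explicit (`redefineQueryToUniverse()`), never automatic.

# Parameters that matter

| parameter | default | meaning |
|-----------|--------:|---------|
| `minOverlap` | 1 bp | minimum shared bases for a region to count as overlapping; raise it to demand substantial overlap |
| FDR scope | per query, all collections | where the BH correction pools p-values |
| odds-ratio smoothing | +0.5 per cell | keeps the log odds ratio finite with zero cells; differs slightly from conditional-MLE estimators in other tools |
| rank ties | competition (1, 2, 2, 4) | deterministic and order-independent |
| output sort | `maxRank`, then p, then set name | byte-reproducible files |

Duplicate regions are collapsed when a set is loaded: the test treats each
region as one independent unit, and a duplicated interval is the same unit
twice. Zero-length intervals are rejected at parse time — they cannot
share a base pair with anything and would still inflate the universe size.
Coordinates are BED-native 0-based half-open on disk and standard 1-based
closed `GRanges` in memory; the conversion happens only in `readBed()` /
`writeBed()`.

# The restricted universe

`buildRestrictedUniverse()` returns the merged union of the query sets
(bookended regions are coalesced, exactly as `mergeRegions()` does). The
merged union — rather than a fragmented disjointification — was chosen so
that the two-query differential-enrichment workflow is well defined: each
query is a subset of the shared universe by construction, and the user
compares the two result tables directly. No contrast statistic is imposed.

# The reference database and its cache

A database is a directory of collections, each with a `regions/` folder of
BED files and an optional `index.txt` (TSV; required column `filename`;
recognized columns `description`, `cellType`, `antibody`, `treatment`;
unknown columns are carried through). Entry order is always lexicographic
by collection, then file name, so results are stable across file systems.

`cacheRegionDB()` stores the parsed sets with a per-file fingerprint
(size + modification time). `loadCachedDB()` rescans the tree, re-reads
`index.txt` fresh, serves unchanged BED files from the cache, re-parses
changed ones, and falls back to a full parse — with a warning, never an
error — when the cache is unreadable. The BED files remain the only source
of truth; the cache can be deleted at any time.

The command-line `--workers` flag is accepted and validated, but execution
is serial: the contract worth testing is that worker count can never change
a byte of output, and the region-pooling overlap engine (one interval-tree
query per analysis rather than one per database set) makes a single worker
fast enough at the intended scales.

# The scenario simulator

`simulateScenario()` generates the test bed the statistical checks run on:

* a universe of `universeSize` equal-length regions placed uniformly at
  random, pairwise disjoint with at least 1 bp between neighbours (a
  uniform draw over all such placements, via the standard bijection with
  subsets);
* a query sampled uniformly from universe regions;
* null database sets, each an independent uniform sample of universe
  regions — so the null distribution of their support is **exactly**
  hypergeometric, by construction, and calibration can be tested without
  approximation;
* optionally a planted set containing
  $\lceil \texttt{plantedFraction} \cdot |Q| \rceil$ query regions plus
  `plantedBackground` non-query universe regions, so its contingency table
  is known exactly in advance.

All randomness flows from one seed; the same configuration reproduces the
same scenario file for file. Defaults are the package's reference study
conditions: 1000 universe regions of 1 kb on two 5 Mb chromosomes, query
size 50, 99 null sets of 50 regions, planted fraction 0.8 with 10
background regions. Null set size 50 mirrors the query so null supports
span a realistic range, and 10 background regions keep the planted set from
being a trivial subset of the query.

What the simulator does **not** emulate: chromatin-domain clustering,
GC- or mappability-driven placement bias, chromosome-specific region
densities, or length heterogeneity. Passing the calibration and recovery
checks therefore demonstrates that the statistics and the overlap engine
are correct under the model's own assumptions — not that p-values on real,
clustered data are exact (they are not; see above).

# Numerical choices

* The hypergeometric tail is computed by `stats::phyper`, which works in
  log space and is stable for margins far beyond $10^6$; results are
  clamped into $(0, 1]$.
* The exact-test implementation is checked against exhaustive enumeration
  of hypergeometric point masses (via `lchoose`) over **all** 2×2 tables
  with every margin ≤ 20 — 35,651 tables — to within $10^{-12}$.
* The overlap engine is checked against a brute-force all-pairs oracle on
  500 fuzzed region-set pairs (up to 500 regions each) at
  `minOverlap` ∈ {1, 2, 10}.
* Calibration uses 2000 null sets (fraction of raw $p \le 0.05$ must stay
  below 0.075; the test is conservative because the support is discrete),
  and recovery uses 200 seeded replicates of the reference scenario, in
  which the planted set must reach `maxRank` 1 in at least 95% of
  replicates. These sizes keep the full check suite inside a few minutes
  on one CPU while leaving Monte-Carlo error well below the margins being
  tested.
* Chromosome order is plain lexicographic on the name string; any
  deterministic collation would do, and this one needs no genome metadata.

# Limitations

* No strand-aware, gapped, or distance-based association measures; overlap
  is purely coordinate intersection.
* No permutation or segment-shuffling null models; the exact test's
  independence assumption is the model.
* No genome-build conversion; queries, universe and database must share a
  build, and the diagnostics only catch naming mismatches.
* BED3 in, TSV out; other formats are out of scope.
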