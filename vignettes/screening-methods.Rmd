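---
title: "Similarity-based screening of herbal compound libraries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-based screening of herbal compound libraries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npscreen)
```

## The screening problem

Multi-compound herbal medicines pose a characteristic discovery problem:
a library of on the order of a hundred chemically related compounds, a
small subset with literature-documented activity against the indication
of interest, and no assay budget to test the rest. `npscreen` implements
the standard network-pharmacology answer, a four-stage funnel:

1. **Curation.** Ingest the compound table, validate and canonicalize
   every structure, merge duplicates, and split the library into
   *known actives* and *candidates*.
2. **Activity transfer.** Compute circular fingerprints, score every
   candidate by its average Tanimoto similarity to the known actives,
   select candidates whose average exceeds a threshold, and build the
   bipartite similarity network for visual inspection in Cytoscape.
3. **Target aggregation.** Pool per-compound target-prediction tables
   (SwissTargetPrediction-style probability scores) and retain targets
   that are predicted consistently across compounds.
4. **Enrichment.** Test the retained target set for over-representation
   in pathway/disease gene-set collections from two annotation sources
   and report the pathways shared by both sources' top ranks.

The guiding assumption is guilt-by-association: a candidate structurally
close to several compounds with demonstrated activity is itself a
plausible active. The package does not validate that assumption — it
makes the procedure that encodes it reproducible and testable.

## Fingerprints and similarity

Structures are parsed, canonicalized (isomeric SMILES; stereochemistry
distinguishes many glycosylated flavonoids) and fingerprinted through
OpenBabel. Fingerprints are extended-connectivity (circular) binary
vectors: each atom's neighborhood is grown over `radius` iterations of
bond connectivity and hashed; `radius = 2` — the ECFP4 dialect — is the
default and the field's convention for ligand-based similarity. The
toolkit's native 4096-bit vectors are OR-folded to `n_bits = 2048` by
default, the dominant folded length; both parameters are configurable
(`n_bits` must divide 4096). Whether chirality contributes to the atom
environments is a property of the toolkit's ECFP implementation;
canonicalization keeps stereo annotations so that equivalent writings of
one molecule always fingerprint identically.

Similarity between fingerprints A and B is the Tanimoto coefficient

$$T_c(A, B) = \frac{|A \cap B|}{|A| + |B| - |A \cap B|},$$

computed from integer bit counts with a single final division, so the
value is exact to double precision. Two all-zero fingerprints compare as
0 by convention (the formula is 0/0): featureless structures should
never be called similar.

## Threshold semantics

The procedure's wording fixes which side of each threshold is included,
and the package follows it literally:

| quantity | rule | boundary |
|---|---|---|
| network edge | $T_c \ge 0.4$ | 0.4 **included** |
| candidate selection | average $T_c > 0.4$ | 0.4 **excluded** |
| target retention (score) | mean score $> 0.1$ | 0.1 **excluded** |
| target retention (support) | compounds $> 2$ | 2 **excluded** |

Averages of exactly representable ratios are not themselves exactly
representable in binary doubles (`mean(c(0.6, 0.2))` evaluates a hair
above 0.4), so all threshold comparisons carry a $10^{-9}$ guard: strict
comparisons require exceedance by more than the guard, inclusive ones
tolerate a deficit up to it. The guard is far below any meaningful
similarity difference and exists purely to pin boundary cases to the
documented side.

Candidate averages run over **all** known actives by default, matching
the procedure's phrasing; a `neighbors_only` mode (average over knowns
connected at the edge threshold, 0 and never selected when there is no
neighbor) is provided because published per-candidate similarity tables
are sometimes neighbor averages — the two modes can be reported side by
side. Ranking sorts selected candidates by decreasing average, ties
broken lexicographically by identifier for determinism. Commercial
availability, the screen's second selection criterion, is an input flag
carried through the score table and never inferred.

Isolated compounds (no edge at the threshold) are excluded from network
exports but retained in score tables; this mirrors how published
interaction figures show fewer known-active nodes than the library
contains.

## Target aggregation

"Average score" is interpreted as the mean over the compounds that
predict the target, not over the whole library: prediction services emit
per-compound probability lists, and averaging in zeros for non-predicting
compounds would make a 0.1 threshold unreachable in any realistic
library. Under this definition the support filter and the score filter
commute, which the tests assert. "More than two related compounds" is
read strictly as at least three. Gene symbols are the aggregation key;
UniProt accessions are carried as annotation only. Duplicate
(compound, target) rows collapse to their maximum score before
aggregation.

## Enrichment and cross-source overlap

Over-representation uses the one-sided hypergeometric upper tail

$$p = \sum_{i=k}^{\min(K,n)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}$$

with $N$ the universe size, $K$ the set size, $n$ the query size inside
the universe and $k$ the overlap. While $\binom{N}{n} < 2^{53}$ the sum
is evaluated with integer-valued binomials (every term is bounded by the
denominator, so double arithmetic is exact); larger instances fall back
to `stats::phyper`. The conservative EASE variant (overlap decremented
by one) is a toggle, default off. The universe defaults to the union of
a collection's members and is configurable, since screening studies
rarely state a background. Benjamini–Hochberg q-values are attached via
`stats::p.adjust`. Rankings use $-\log_{10} p$ (base 10 matches how both
common enrichment engines display significance); ties break by set name.

The cross-source rule takes the top `k = 5` sets of each source and
intersects their names. Because annotation sources brand the same
pathway differently ("HIF-1 Signaling" vs "HIF-1 signaling pathway"),
matching defaults to a normalized key: case-folded, punctuation
stripped, and the trailing "signaling pathway" / "signaling" /
"pathway" suffixes removed. Exact matching is available.

## The synthetic study

The generators produce data with the statistical structure the screen
assumes, so recovery is measurable against a known truth:

* **Library** (`generate_library`): known actives are flavone/flavonol
  scaffolds decorated at two ring positions with small substituents
  (hydroxy, methoxy, alkyl, halogen, acetoxy...); analogs reuse a parent
  known's scaffold with `analog_distance` substituents swapped; decoys
  come from a disjoint aliphatic family. Defaults — 5 knowns, 10
  analogs, 10 decoys — are the package's reference conditions.
  Substituents are deliberately small relative to the shared scaffold:
  that keeps the known-active family homogeneous, which is what makes an
  "average similarity to all knowns" criterion meaningful in the first
  place. The generator verifies its planted properties before returning:
  every analog's similarity to its parent is at least 0.4 **and** its
  average over all knowns strictly exceeds 0.4 (the selection criterion),
  and every decoy stays below 0.4 to every known; failures are redrawn
  within a bounded attempt budget and reported as generation errors
  beyond it. Verification is skipped when sweeping `analog_distance`
  past the threshold, where failing the criterion is the point: distance
  1 swaps one substituent, 2 swaps both, 3 replaces the scaffold
  entirely, yielding a monotonically non-increasing sensitivity curve.
* **Predictions** (`generate_predictions`): planted targets are
  predicted for 3–5 compounds with scores uniform on (0.15, 0.8), so
  both retention filters hold by construction; background targets fail
  the support filter (1–2 compounds) or the score filter (scores below
  0.08) in equal measure.
* **Gene sets** (`generate_genesets`): both collections carry one
  planted set holding every retained target symbol under differently
  formatted names; background sets draw from per-source filler symbols
  (occasionally touching one query symbol, so background p-values are
  not all degenerate), with per-source name stems so only the planted
  set can match across sources.

Every draw comes from one seeded generator per specification
(`withr::with_seed`), so generation is a pure function of the spec and
byte-identical across runs and platforms.

What passing on synthetic data does **not** show: real herbal libraries
have continuous similarity structure rather than a planted gap around
0.4, real prediction scores are correlated across related compounds, and
real gene-set collections overlap heavily. The synthetic study validates
the machinery — thresholds, aggregation, rankings, determinism — not the
biological merit of the screen.

## The pipeline

`run_pipeline()` executes the four stages from a validated configuration
(`run_config()`, YAML round-trip via `read_run_config()` /
`write_run_config()`) whose thresholds default to the published screen's
values. Every stage writes its table under the output directory, and the
run report records each filter's in/out counts so the whole funnel is
auditable; the pipeline itself draws no random numbers, making reruns
byte-identical (the report's timestamp line aside). `simulate_study()`
writes a complete synthetic study — inputs, truth tables and a ready
configuration — making the end-to-end path one call long. A thin
command-line wrapper (`inst/cli/npscreen.R`, subcommands `simulate` and
`run`) exposes the same two entry points to shell users; the individual
stages are package functions.

Problem sizes used throughout the tests and the reproduction script are
the reference conditions above (25 compounds, 100 similarity pairs, 30
targets, two 20-set collections over ~300-symbol universes); exhaustive
hypergeometric checks enumerate every instance with a universe of at
most 12 genes.

## Known limitations

* OpenBabel's ECFP implementation hashes atom environments differently
  from other toolkits, so absolute bit positions (and, mildly, Tc values
  near a threshold) are toolkit-specific; reproduction of a published
  screen's exact pair counts is expected to be sensitive to the
  fingerprint dialect.
* The compound-class vocabulary is fixed to nine labels; unrecognized
  labels are coerced to `other` rather than rejected.
* Gene-symbol matching is exact (case-sensitive); no alias resolution is
  attempted.
* CAS numbers are opaque annotations; no structure resolution is
  performed at run time, keeping the package fully offline.
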