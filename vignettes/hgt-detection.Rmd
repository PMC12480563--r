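---
title: "Detecting horizontal gene transfer by sister-clade scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontal gene transfer by sister-clade scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Horizontal gene transfer (HGT) into or out of a focal lineage leaves a
topological signature in per-orthogroup gene trees: a focal ("query")
sequence that nests robustly inside a clade of phylogenetically distant
sequences, rather than next to its expected sister lineages. `hgtscan`
detects this signature at corpus scale. Its inputs are (a) one gene tree
per orthogroup, in the newick dialect of fast approximate-ML tree builders
where internal-node labels are branch supports in [0, 1]; (b) a taxonomy
map assigning every leaf one of four roles — `query` (focal proteome),
`ingroup` (other focal-lineage sequences), `sister` (the focal lineage's
closest relatives), or `outgroup` with a major-lineage label (e.g.
Stramenopila, Alveolata, Opisthokonta, Bacteria, Viruses).

## The classifier

For each query leaf the walk proceeds through nested clades, from the
query's parent up to the root, after two preprocessing steps:

1. **Rooting.** Gene trees from approximate-ML tools are unrooted. The
   default `farthest_leaf` strategy roots on the terminal edge of the leaf
   with maximal path length from the first query (ties broken
   lexicographically) — a deterministic stand-in for outgroup rooting that
   maximizes walk length. `midpoint` and `as_is` are available; for deeply
   placed queries the two automatic strategies can disagree, which is why
   both ship. Re-rooting never relabels a bipartition's support.
2. **Support collapse.** Every internal edge with support at or below the
   cutoff (default: collapse unless support > 0.85, the strict reading of
   the upstream bootstrap threshold) is contracted into a polytomy, so that
   only well-supported clades act as evaluation units. Absent supports
   (leaf edges, the root) count as resolved.

At each nested clade the walk accumulates cumulative counts of sister
leaves and per-lineage outgroup leaves, and stops at the first clade where
a criterion fires, with precedence `ancestral` > `ancestral_hgt` >
`single_hgt`/`multi_hgt`:

* `ancestral` — at least `min_sisters` (default 5) sister sequences:
  vertical inheritance.
* `ancestral_hgt` — at least one sister plus at least
  `min_outgroup_per_lineage` (default 3) outgroup sequences from one major
  lineage: a transfer predating the focal/sister split.
* `single_hgt` / `multi_hgt` — no sisters, only ingroup plus at least 3
  outgroup sequences from major lineages; `single` when every outgroup leaf
  in the clade shares one lineage (a ≥ 90%-majority reading is available
  via `single_lineage_rule = "majority"`), `multi` when two or more
  lineages are present and at least one reaches the per-lineage minimum.
* `ingroup_only` — no criterion fired and the whole tree holds only
  query/ingroup leaves.
* `undetermined` — no criterion fired in a mixed-composition tree. This
  sink category is deliberate: the four literature categories do not cover
  walks that exhaust the tree, and forcing a label would fabricate calls.

The evaluation is equivalent whether criteria are read as "found so far"
or "found in the current clade", because clades are nested and counts
cumulative. Ties between `ancestral` and HGT criteria at one step (possible
at polytomies) resolve to `ancestral`: a full complement of sisters is
stronger evidence of vertical descent than co-occurring outgroups.

## Direction and events

Within a stopping clade, rooted at its own ancestral node, the focal +
sister leaves either form one monophyletic group nested among the outgroup
leaves (ingroup monophyly) or branch interleaved with them. Monophyly
supports the focal lineage being the *acceptor* of the transfer; otherwise
direction is reported `unresolved`. The test uses topology only.

Per-query calls are then deduplicated into events: HGT-category walks of
one orthogroup are grouped by the query+ingroup+sister leaf set of their
stopping clade (so calls differing only in outgroup resolution merge; full
leaf-set keying is available via `event_key = "full"`). Events never merge
across orthogroups. Gene totals are conserved: the sum of member genes over
events equals the number of HGT-category walk results, so events ≤ genes
always.

## Validation statistics

Two checks mirror standard practice for HGT call sets:

* **Contig-length artifact check.** If HGT candidates sat on short contigs
  they could be uncaught assembly contamination. `contig_length_check()`
  compares contig lengths of HGT genes against ancestral genes with a
  two-sided Mann-Whitney U test and the Vargha-Delaney A effect size
  (A = U/(n1·n2), 0.5 = stochastic equality); `A >= 0.5` or a
  non-significant p reads "no-shortening signal".
* **Donor-lineage enrichment.** For each lineage, its share among non-focal
  leaves inside a tree's HGT stopping clades (x_t) is paired with its share
  among non-focal leaves of the whole tree (y_t); a one-sided (greater)
  Wilcoxon signed-rank test on d_t = x_t − y_t, BH-adjusted across
  lineages, asks whether inferred donors are over-represented in HGT clades
  relative to each tree's own taxonomic composition. The one-sided Wilcoxon
  is read as a *paired* signed-rank test because the baseline is explicitly
  per-tree; a rank-sum variant of the primitives is available directly. The
  pairing unit, and whether proportions or counts are compared, is an
  interpretation — the per-tree proportion reading is the one implemented.

The rank primitives are implemented in-package with exact small-sample
enumeration: the Mann-Whitney null distribution by a subset-sum count over
doubled midranks (tie-exact) for n1+n2 ≤ 20, and the signed-rank
distribution over all 2^m sign assignments for m ≤ 20. Beyond the cutoffs
both switch to normal approximations with tie-corrected variance and
continuity correction, matching common implementations at corpus scale
while keeping small-instance behaviour exactly enumerable. Zero differences
are dropped before ranking (Wilcoxon's original treatment); ties receive
midranks.

## The synthetic generator

`simulate_tree()` grows a random bifurcating backbone by seeded uniform
random joins (Yule-type; topological realism is not the test target) and
plants one scenario per tree: `vertical`, `ancient_hgt`,
`recent_hgt_single`, `recent_hgt_multi`, or `ingroup_only`, with known
truth. Defaults are 40 leaves, 2 queries, 2 ingroup paralogs, donor clades
one leaf above the classifier minimum, point-mass supports at 1.0 and zero
label noise — a clean corpus on which every planted call is recoverable.
Design choices that matter:

* **Planted contiguity.** Focal leaves are planted as one contiguous clade
  inside the donor clade, so planted HGT trees are ingroup-monophyletic and
  the planted direction is always `acceptor`.
* **Minority-donor placement** (`recent_hgt_multi`). Minority-lineage donor
  leaves branch closest to the focal clade and are capped below the
  per-lineage minimum, so no pure-lineage sub-clade can fire `single_hgt`
  before the mixed clade fires `multi_hgt`.
* **Rooting anchor.** Branch lengths are i.i.d. Exp(1), except that one
  backbone outgroup leaf per tree has its terminal branch extended beyond
  the longest query-to-leaf path (plus an Exp(1) margin). This emulates a
  distant homolog and pins farthest-leaf rooting outside the planted
  clade. Without it, rare length draws root inside the donor clade, where
  the first qualifying clade can differ from the planted one — a property
  of rooting, not of the walk.
* **Label noise** redraws a leaf's role and lineage jointly, uniformly from
  the other options, stressing both the count thresholds and the monophyly
  test.
* **Support noise.** A Beta support model is available for exercising the
  collapse step; with Beta(8, 2) about 60% of edges fall at or below 0.85
  and collapse under the default cutoff.

What the generator does *not* emulate: sequence-level evolution (no
alignments, no inferred trees), correlated support errors, paralog
structure beyond flat ingroup leaves, or incomplete taxon sampling. Passing
recovery tests therefore demonstrates correctness of the decision
procedure under its stated assumptions, not end-to-end accuracy on real
proteome-scale data.

## Numerical and procedural choices

* Supports are never invented: unlabeled edges carry absent support and are
  treated as resolved. Labels above 1 are read as bootstrap percentages and
  rescaled with a warning; above 100, rejected.
* "Highly supported" is strict (`support > threshold`), per the upstream
  convention; `strict_greater = FALSE` relaxes to ≥.
* All tie-breaks (farthest-leaf rooting, walk order over queries, event
  ordering) are lexicographic, making every pipeline product byte-stable
  across runs.
* Degenerate inputs: query-free trees are refused by the walk (flagged at
  annotation); clades without outgroup leaves make the monophyly test
  undefined (an error, not a default); all-zero difference vectors make the
  signed-rank test undefined; malformed corpus trees are skipped, logged
  and counted in the run manifest rather than aborting corpus runs.
* Problem sizes used by the shipped validation: oracle comparison against a
  brute-force clade enumerator on random 4-8-leaf rooted trees (50,000
  sampled instances in the test suite); recovery and determinism on
  200-tree corpora (5 scenarios × 40 trees); noise degradation over noise
  rates {0, 0.05, 0.1, 0.2} × 10 seeds; enrichment calibration over
  lineage-label permutations (rates of adjusted p < 0.05 compared against
  the nominal level with a 3-standard-error allowance).

## Worked example

```{r, eval = FALSE}
library(hgtscan)

corpus <- simulate_corpus(default_mixture(40), seed = 42)
scan <- classify_corpus(corpus)
evaluate_recovery(scan, corpus)
#> Recovery over 200 trees: category accuracy 1.000, direction accuracy 1.000

head(lineage_enrichment(scan$events, scan$trees), 2)
#>        lineage n_trees    W            p       p_adj    mean_x    mean_y
#> 1 Stramenopila     120 7260 9.457785e-22 6.62045e-21 0.7461111 0.2321759
#> 2    Alveolata     120 3611 4.571817e-01 1.00000e+00 0.1333333 0.1412037
```

The planted donor (Stramenopila) is the only enriched lineage; every other
lineage's share inside HGT clades matches its tree-wide share.

## Known limitations

* The rooting convention of the original tree-walk literature is unstated;
  calls for deeply placed queries can depend on it. Both automatic
  strategies are shipped and the choice is surfaced as a parameter rather
  than hidden.
* "5 sister sequences" is counted as sequences, not distinct taxa.
* For `multi_hgt`, the per-lineage minimum is required of at least one
  lineage (with the total also at the minimum), the permissive reading; the
  strict every-lineage reading can be recovered by raising
  `min_outgroup_per_lineage`.
* Events are never merged across orthogroups, so shared donor clades split
  over several orthogroups count once per orthogroup.
* The enrichment test conditions on the detected stopping clades; it
  validates composition, it does not re-test detection.
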