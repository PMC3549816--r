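---
title: "Unraveling overlapping deletions: model, scoring and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unraveling overlapping deletions: model, scoring and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delclust)
```

## The generative model

A paired-end library sequences both ends of DNA fragments whose length is
approximately normal with mean $\mu_f$ and standard deviation $\sigma_f$
(per sample; the package default used throughout the documentation is
$\mu_f = 300$, $\sigma_f = 35$, with 100 bp reads). When a fragment spans a
deletion breakpoint in the donor, its reads map to the reference in proper
orientation but at an outer distance $d$ inflated by the deleted bases. A
pair is treated as *stretched* when $d \ge \mu_f + 3\sigma_f$; the implied
deletion size is then distributed $\mathrm{Normal}(d - \mu_f, \sigma_f)$.

In the (deletion start $x$, deletion end $y$) plane, a stretched mapping is
compatible exactly with the triangle

$$\{(x, y) : l \le x,\; y \le r,\; y \ge x\},$$

where $l$ is the position after the left read's last base and $r$ the first
position of the right read. Over this triangle sits a Gaussian ridge: the
density of the size $s = y - x$. We use 0-based half-open coordinates
internally ($l$ = first position where the deletion may start, $r$ = first
position that may *not* be deleted); reports convert to 1-based inclusive.
This convention is our choice (it matches BAM-library conventions); the
representation itself does not depend on it.

## Cluster algebra

A cluster of $n$ mappings is summarized by $(n, l, r, \mu, \sigma)$.
Merging clusters $C_1, C_2$ follows an average-link, intersection-of-bases
rule:

$$n = n_1 + n_2,\quad l = \max(l_1, l_2),\quad r = \min(r_1, r_2),\quad
\mu = \frac{n_1\mu_1 + n_2\mu_2}{n},$$
$$\sigma^2 = \frac{n_1\sigma_1^2 + n_2\sigma_2^2}{n}
 + \frac{n_1 n_2 (\mu_1 - \mu_2)^2}{n^2}.$$

The variance rule aggregates the two sub-populations: it equals the mean of
the variances when the clusters agree in size ($\mu_1 = \mu_2$, $n_1 =
n_2$) and broadens as they disagree. Two properties are deliberate:

* $\sigma$ does **not** shrink like $\sigma/\sqrt{n}$. A cardinality-
  dependent width would make small clusters systematically broader and
  therefore easier to merge, so merge order would be driven by cluster size
  rather than similarity (and scores would underflow for large clusters).
* Parameters are updated incrementally, pairwise. For unequal weights the
  final $\sigma$ can depend on merge order; this is inherent to the
  published update rule and we treat the pairwise contract as normative
  (the test suite checks the pairwise algebra, commutativity, convexity of
  $\mu$ and monotone growth of $\sigma^2$ in $|\mu_1-\mu_2|$, not
  order-invariance).

## Similarity score

Each cluster defines a volume $V(C)$: the ridge height integrated over the
triangle. Since the height is constant along anti-diagonals, $V$ reduces to
a sum over sizes; we use the discrete 1 bp grid

$$V(C) = \sum_{s=0}^{w-1} (w - s)\,\phi(s;\mu,\sigma), \qquad w = r - l,$$

with $\phi$ the normal density. This mirrors the anti-diagonal traversal
geometry and keeps each score computation at $O(r-l)$. The similarity is
the normalized intersection

$$\mathrm{sim}(C_1, C_2) =
  \frac{V(C_1) \cap V(C_2)}{\max\{V(C_1), V(C_2)\}} \in [0, 1],$$

where the intersection volume uses the pointwise minimum of the two ridges
over the intersected base. It is 0 iff the bases do not overlap, 1 iff the
clusters are identical, and — because the ridge runs parallel to the
diagonal — more forgiving of staggered locations than of size differences:
staggered mappings covering one breakpoint should cluster, mappings
implying different sizes should not.

Numerical choices:

* the line length at size $s$ is $(w - s)$, the continuous segment length;
  the $\sqrt2$ anti-diagonal constant is omitted (it cancels in the ratio);
* sizes run over $s \in [0, w-1]$ — the $s = w$ term has zero length, so
  including it would change nothing;
* densities that underflow to zero are left at zero: a pair whose score
  underflows despite touching bases behaves as non-overlapping (the stop
  threshold removes such pairs anyway);
* volumes are cached on the cluster record and computed once per cluster
  lifetime (asserted via operation counters in the tests);
* the discrete sums agree with fine-grid (0.01 bp) numerical integration to
  well under 0.5% relative error whenever $\sigma \ge 5$ and the ridge sits
  inside the triangle with a $3\sigma$ margin — the regime of real
  clusters, since a stretched singleton always has $\mu \ge 3\sigma$ and
  merging keeps $\mu$ a convex combination. Closed-form Gaussian integrals
  would be admissible only as an optimization; the discrete sum is the
  definition.

## Regions and the clustering engine

Mappings are partitioned into *regions*: connected components of genomic
footprint overlap (footprint = outer span of the pair, half-open; touching
footprints do not overlap). Regions cannot share a deletion, so they are
clustered independently. For BAM input the true outer coordinates are
available; for plain mapping tables the outer start is reconstructed
assuming equal-length reads. The footprint is only used for partitioning,
where an over-wide footprint can at worst join two regions that would
anyway not exchange merges (their triangles cannot overlap).

Within a region, every mapping starts as a singleton cluster; the engine
repeatedly merges the highest-scoring pair while the best score strictly
exceeds the threshold $S_{\min}$. Candidate pair scores are held in a pool
with lazy invalidation (entries naming merged-away clusters are skipped);
after each merge, scores are computed only against clusters whose triangles
overlap the new cluster — scores to the rest are provably zero. Equal
scores are broken toward the lexicographically smaller (older) cluster-id
pair, making the procedure deterministic for a fixed region regardless of
input order (mappings are sorted by coordinates before ids are assigned).
The suite checks this engine against a naive implementation that rescans
all pairs at every iteration, on random regions of up to 30 mappings.

## The stop threshold

Because a normal density is never exactly zero, overlapping triangles
always have positive similarity; a stop threshold is required. Instead of a
fixed constant, the data are examined once, globally: for every mapping we
record the smallest strictly positive similarity between its singleton and
any other mapping's singleton in its region, and $S_{\min}$ is the median
of these minima. For an even count we take the lower central value, so the
threshold is always a score actually observed between two mappings. If no
positive pair exists at all the threshold falls back to 0.5 — an arbitrary
value, logged, and irrelevant since no merge is possible in that case.
A user-supplied `s_min` overrides the estimate.

This estimator is intentionally data-dependent: on genome-scale data the
per-mapping minima are dominated by weak, barely-overlapping and erroneous
mappings, which places the median well below the scores that connect
mappings of a common deletion. On small, idealized simulations where every
mapping in a region belongs to the same deletion, the minima are themselves
strong same-deletion scores and the estimate lands higher — in which case
late merges (a tight cluster absorbing its last, peripheral mappings, whose
scores are deflated because the tightened triangle clips the ridge at its
upper corner) can fall below it and leave small satellite clusters. The
simulation harness exposes this honestly; see "What the simulator does and
does not emulate" below. `cluster_deletions(..., s_min = )` is the
documented control when the input is known to be cleaner than genome-scale
data.

## Reporting

`tidy()` and `write_cluster_table()` report one row per cluster —
singletons included, flagged via `below_min_support` — with 1-based
inclusive boundaries, $\mu$, $\sigma$, $n$ and per-sample counts in
`n_<sample>` columns; the members file lists mapping ids per cluster.
`plot_region()` draws each mapping triangle in its sample's color with the
ridge shaded in at most 16 gray bands (edges at equal probability
quantiles of the size distribution), overlays every supported cluster as a
yellow trapezoid spanned by $l$, $r$, $\mu \pm 3\sigma$ — clipped to the
diagonal and to the triangle, a choice we make for readability where the
band exceeds the base — labeled with $n$, and dots the outlines of
unsupported mappings. Rendering never mutates the fit.

## Input filters

The BAM reader keeps a pair when: both mates are mapped to the same
chromosome in forward–reverse orientation with the left mate forward; both
mapping qualities are at least 20 (applied per mate — the stricter of the
two possible readings) and positive; both CIGAR strings are a single match
run (no insertions, deletions, or soft/hard clips); aligner tags indicating
alternative placements (`X0`, `XA`, `NH` by default, configurable) indicate
a unique best hit; the outer distance is at least $\mu_f + 3\sigma_f$; and
the inner boundaries are non-degenerate. Filtered pairs are counted, not
errors. Exact-duplicate collapsing is available but off by default —
duplicate marking is normally an upstream concern.

## What the simulator does and does not emulate

`simulate_truth()` places single-deletion loci and overlapping pairs
uniformly on one chromosome with a minimum inter-locus gap (default
1000 bp, enough to keep loci in separate regions), sizes log-uniform over
$[105, 10^4]$ by default — 105 bp being the smallest size reliably visible
to paired-end evidence under the default fragment model; an empirical size
list can be supplied instead. Pair partners overlap by a uniform fraction
(0.2–0.8 by default, exposed as parameters) of the smaller partner on a
random side; zygosity mode A puts both partners homozygously in one diploid
copy each (haplotypes {0,1} / {2,3}), mode B makes the second partner
heterozygous ({0,1} / {2}); singles are homozygous in the first copy.
Coverage is interpreted per haplotype.

`simulate_mappings()` then places fragments along each donor haplotype at
the rate implied by coverage, draws lengths from the fragment model
(truncated below at two read lengths), and projects donor coordinates back
to the reference: a fragment whose reads flank one or more breakpoints
yields a stretched mapping with `span_d` equal to its length plus all
deleted bases spanned; a fragment with a breakpoint inside a read would not
align gap-free and is dropped; fragments spanning nothing are concordant
and omitted by default. Options add uniform spurious mappings
(`noise_rate`, per true deletion, with log-uniform mis-stated sizes) and
the stretched upper tail of the fragment-length distribution
(`emit_tails`): pairs longer than $\mu_f + 3\sigma_f$ that span no
deletion yet pass the length filter, as they do in real libraries.

The simulator is exact at the mapping level but idealized below it: there
are no read sequences, no sequencing errors, no alignment ambiguity, no
repeat-induced mis-mappings, and (by default) none of the weak incidental
mappings that blanket real genomes. Consequently passing tests demonstrate
the geometry, the score, the engine and the evaluation logic — and
parameter recovery under clean evidence — but *not* robustness to
alignment artifacts, and the data-driven threshold estimate on these clean
instances is systematically higher than it would be on genome-scale data
(see "The stop threshold"). The test suite therefore checks threshold
estimation against its brute-force definition, checks engine correctness at
the estimated threshold, and checks end-to-end recovery both through the
full default pipeline (cluster-level recovery of each simulated deletion
within its reported trapezoid) and with an explicit threshold in the
method's working range.

## Evaluation

Truth loci are connected components of reference overlap among simulated
deletions: a single deletion or an overlapping pair. A supported cluster
*matches* a truth deletion when its reported trapezoid contains it —
$l \le \mathrm{start}$, $\mathrm{end} \le r$ and
$|\mathrm{size} - \mu| \le 3\sigma$ — a rule chosen because it uses exactly
the fields the cluster table reports. Each supported cluster is assigned to
at most one locus (by matching, else by breakpoint-region overlap); clusters
away from any truth form their own no-truth loci. The predicted kind of a
locus is the number of distinct supported clusters assigned: none, single,
pair, or multi. Rates follow the printed definitions:

$$TPR_1 = \frac{\#\text{truth single predicted single}}{\#\text{truth single}},\qquad
FPR_1 = \frac{\#\text{predicted single at non-single loci}}
             {\#\text{truth pairs} + \#\text{no-truth loci with a prediction}},$$

analogously $TPR_2$/$FPR_2$ for pairs; zero denominators yield `NA`, never
a crash. Over correctly identified pairs (both partners matched by distinct
clusters), the mis-assignment rate is the pooled fraction of member
mappings sitting in the cluster that does not correspond to their
haplotype-of-origin deletion; mappings without a truth annotation are
excluded from both numerator and denominator.

## Problem sizes and determinism

The test suite and the acceptance script work at desk scale by design: 100
random regions of up to 30 mappings for the engine-vs-oracle check, 200
random clusters for the volume oracle, 100 single-deletion loci on a 3 Mb
chromosome and 50 single + 25 pair loci on 1.5 Mb for the end-to-end
scenarios, at 20× per-haplotype coverage. Every stochastic step runs under
an explicit seed, and all simulations in `scripts/acceptance.R` derive
their seeds from the `--seed` argument.

## Known limitations

* Deletions only: no insertions, inversions, translocations, or copy
  number; no split-read or coverage evidence.
* Merged $\sigma$ can depend on merge order (inherent to the incremental
  update rule).
* The breakpoint resolution of a call is the interval $[l, r]$ with a size
  posterior, not a base-pair breakpoint; very similar overlapping
  deletions remain indistinguishable in principle.
* The threshold estimator presumes data in which weak mapping pairs are
  abundant; on small clean inputs, prefer an explicit `s_min` (the engine
  itself is insensitive to this choice over orders of magnitude once the
  threshold is below same-deletion link scores).
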