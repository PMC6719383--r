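---
title: "mitoarch: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitoarch: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mitoarch` asks whether nuclear genes that respond to mitochondrial
haplotype substitution are randomly placed — along chromosomes, in
interaction networks, in co-expression modules, and in developmental time —
or structured. This vignette documents the statistical models, every tunable
parameter that matters, what the synthetic generator does and does not
emulate, and the design choices made where the design was genuinely open.
It states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## Differential expression model

Counts for gene g in sample i are modelled as negative binomial,
$y_{gi} \sim \mathrm{NB}(\mu_{gi}, \phi_g)$ with
$\mathrm{Var} = \mu + \phi\mu^2$, log link and a per-sample library-size
offset. Three contrasts mirror a mitonuclear panel of H haplotypes:

- *haplotype ANODEV*: one mean per haplotype vs a common mean (df = H − 1);
- *species*: haplotypes pooled by source species, two means vs one (df = 1);
- *G×G*: for a haplotype pair across two nuclear backgrounds, the
  interaction term of `mito * nuc` vs `mito + nuc` (df = 1).

The statistic is `lr = 2(ℓ_full − ℓ_reduced)` clipped at zero, with p from
the upper χ² tail at the contrast's df. Fits use `stats::glm.fit` with
`MASS::negative.binomial(1/φ)` (Poisson at the `1e-8` dispersion floor).

**Dispersion.** φ is a per-gene method-of-moments estimate: within each
design group, the variance of offset-normalized counts in excess of the
Poisson expectation is attributed to the quadratic term, pooled over groups
with weights (n−1), floored at `1e-8`. This deliberately replaces shrinkage
chains (common → trended → tagwise) used by dedicated DE packages: the
downstream stages consume only (lr, p, fdr), so the architecture is
unchanged, but the cost is known and documented — with 4 replicates per
group the null LRT is mildly anticonservative (empirical P(p < 0.05) around
0.07–0.10 instead of 0.05). The calibration suite checks approximate
uniformity by KS at α = 0.01, which this satisfies; analyses that need exact
type-I control at small n should use a shrinkage-based tool.

**Offsets.** One log offset per sample, by the median-of-ratios method
(median across everywhere-expressed genes of the ratio to the per-gene
geometric mean, centred on the log scale). Plain total-count offsets are
biased when a visible fraction of genes is strongly differential — at desk
scale (10% of genes at fold 4) the bias made true nulls reject at 3–7× the
nominal rate — while the median ratio is robust to a differential minority.
This is still a single library-size offset per sample; no trended or
gene-specific normalization factors are estimated.

**Filtering.** Genes without CPM ≥ 1 (configurable) in at least
min-group-size samples are dropped before testing, with a logged count; the
originating study does not state its rule, so the default is explicit and
configurable. Non-converged fits are flagged (`p = NaN`) and excluded
downstream with a logged count. BH-FDR is a direct step-up implementation
(`q(i) = min_{j≥i} p(j)·m/j`), with NA p-values excluded from m and
reinserted.

## Max-gap physical clustering

A cluster is a maximal run of ≥ `min_size` (default 2 — a singleton is not a
cluster) test genes on one arm with at most `max_gap` (default 5)
non-members between consecutive members. Gaps are counted in gene ranks, not
base pairs, so the statistic depends only on gene order. Positional
uniformity is tested per arm with a two-sided one-sample KS test on
midpoints scaled by the arm span (physical position, not rank — "uniform
along the arm" is a statement about coordinates; a rank-based variant is a
one-line change at the call site since ranks can be fed in as positions).
Significance of the overall clustering uses `n_iter` random gene lists of
the observed size; empirical p-values carry the +1 correction, so the
smallest reportable value is 1/(n_iter+1) — a result of 0.001 at
n_iter = 999 means "below the resolution of the null sample", not an exact
probability. Gene midpoints `(start+end)/2` define all linearization;
internal coordinates are 0-based half-open (BED convention; GFF3 input is
shifted on read). Genes lacking coordinates are kept for network and
enrichment stages but excluded (logged) from clustering.

## Network neighborhood enrichment

Given per-gene attributes (−log₁₀ p from a chosen contrast; missing genes
imputed 0 with a logged count), each node's neighborhood is the unweighted
shortest-path ball of radius d (default 1, always containing the focal
node). The neighborhood attribute sum is compared with `n_perm` random
permutations of the attribute vector over nodes; the empirical p (with +1
correction, and a tolerance so floating-point-tied sums count as
exceedances) gives heat = −log₁₀ p. Design choices: the null is a plain
attribute shuffle — the simplest exchangeable "random expectation model" —
rather than degree-preserving rewiring; flagging uses the raw empirical p at
α (default 0.05), with a BH-adjusted column provided for stricter
selections; layout-based neighborhoods of the original SAFE method are not
reproduced, as radius-d balls express the same "local interaction
neighborhood" idea without a force-directed embedding. Per-node degree and
neighborhood connectivity (mean degree of direct neighbors; NA for isolated
nodes) support Welch comparisons between significant and non-significant
gene sets.

## Focal-gene ranking

Interaction lists are preprocessed exactly as the sensitivity-hub analysis
requires: every edge present in both directions (so the network is
effectively undirected and out-neighbors equal all direct interactors),
edges touching miRNA genes removed, unscored edges removed, duplicates
collapsed. A focal gene's score is the arithmetic mean of the likelihood
ratios of its interactors that have LR values; interactors without LR are
excluded (with a logged count) rather than counted as zeros — imputing zeros
would conflate "untested" with "not differential". Ties in mean LR break
lexicographically so top-n sets are deterministic. The minimum-interactor
filter defaults to 1 and is exposed; `interactor_count_sensitivity` reports
top-list stability across thresholds and the Pearson correlation between
interactor count and mean LR (df = n − 2) so users can verify the score is
not a degree artifact.

## Gene-set enrichment

`hypergeom_overlap` restricts the test list and the annotated set to an
*explicit* universe (never inferred — the universe is the set of genes
observable by both the DE analysis and the annotation resource, and silently
guessing it changes every number), then computes both exact tails of
X ~ Hypergeometric(N, K, n), the expected overlap nK/N and the fold
k/expected. The headline tail follows the fold direction; both tails are
always emitted because over-representation (improper module) and
under-representation (housekeeping, essential genes) are both of interest.
Folds are reported at full precision; any truncation is presentation-layer.
The matched permutation null draws size-n lists without replacement and is
checked against the exact law in the test suite.

## Dendrogram concordance

Expression profiles are clustered with distance 1 − Pearson correlation and
complete linkage (the linkage is fixed by the method being emulated; the
metric is not stated there, so it is a documented, configurable default —
correlation distance is the standard choice for expression profiles).
Zero-variance profiles are excluded with logged ids.

- **Entanglement** between two trees over the same leaves:
  Σ|r^A − r^B|^L / Σ|i − (n+1−i)|^L with leaf ranks r in each tree's
  left-to-right order; 0 = identical orders, 1 = exactly reversed. The norm
  exponent L defaults to 1.5, the convention of the R package that
  popularized the statistic; it is a parameter because nothing in the method
  fixes it.
- **step2side untangling** greedily flips children of internal nodes
  (strict improvement only), sweeping one side then the other; when single
  flips stall on trees below `joint_max_leaves` (default 200), a joint phase
  flips one node on each side simultaneously to escape the local optima
  one-sided rotation cannot leave. Topology and heights never change, so the
  result's entanglement is never above the input's. On ≤ 6 leaves it reaches
  within 0.05 of the exhaustive optimum in ≥ 90% of random instances
  (measured ~93%).
- **Goodman–Kruskal γ**: each leaf pair has a cophenetic merge height in
  each tree; γ = (C − D)/(C + D) over all pairs of leaf pairs, ties skipped.
  Computed from an ordinal contingency table over the ≤ n−1 distinct merge
  heights per tree (O(n²) instead of the O(n⁴) literal enumeration, which
  remains the test oracle). The permutation test shuffles the leaf labels of
  one tree (side configurable, including both) — the natural null of "same
  shapes, no label correspondence"; reported are the null mean, its 95% CI
  and one-sided t-tests against γ = 1 and against the observed value.
- **Cophenetic correlation**: Pearson r of the aligned upper-triangle
  cophenetic matrices; flagged NA when either tree is degenerate (all merges
  at one height).
- **Rolling membership scan**: the leaf order is scored with a w-gene
  (default 50) rolling sum of a 0/1 membership indicator; peak windows
  localize temporally co-expressed hotspots of sensitive genes. The window
  is in genes, not base pairs.

## The synthetic world

The generator plants the structure each stage must recover, at the stated
design scale: 4 mtDNA haplotypes (two per species) × 2 sexes × 2 nuclear
backgrounds × 4 replicates; five Drosophila-like chromosome arms
(23.5–32.1 Mb); NB dispersion 0.1; planted fold change 4 on a 10% effect
fraction split evenly between haplotype, species and G×G classes (G×G =
equal-magnitude, opposite-sign haplotype shifts across the two nuclear
backgrounds — the cleanest realization of an interaction); log-normal
library factors (σ = 0.2) to force offset handling; an improper-module
fraction of 0.204 with a 3.5× planted enrichment (the published scale);
scale-free networks by preferential attachment with hot neighborhoods
seeded — and their membership kept — in the low-degree,
low-neighborhood-connectivity stratum (in a scale-free graph, low-degree
nodes often hang off hubs; leaving hubs inside a "poorly connected" hotspot
would contradict the very pattern the Welch comparisons test); hotspot
attribute boost +3 on the −log₁₀ p scale (each member resembling a
p ≈ 10⁻³ gene over its null draw); 12 developmental stages in 5 contiguous
activity blocks. One master seed spawns stage-keyed child seeds, so any
stage can be regenerated alone and stage order never changes results.

What a green test does **not** establish: the generator has no read-level
noise, no GC or length bias, no batch structure, no correlated genes within
arms beyond the planted clusters, no allele-frequency structure, and
independent genes given the design — real data will be harder on every
stage, particularly the DE calibration. Recovery rates measured here are
upper bounds.

One planted-truth property was sharpened rather than asserted blindly: "any
gene adjacent to a planted high-LR neighborhood ranks above the 90th
percentile" fails structurally for genes whose many null interactors dilute
the mean (measured ~0.83); the suite instead verifies that genes whose
interactor sets are majority-boosted clear the 90th percentile (≥ 0.9) and
that adjacency shifts the whole rank distribution upward (Wilcoxon
p < 0.01 in every replicate).

## Numerical conventions

- Empirical p-values always use the +1 correction; permutation sums tied
  with the observed value (to 1e-9 relative) count as exceedances.
- Ordering ties (p-values, mean LR, midpoints) break lexicographically by
  gene id, so every ranked output is deterministic across platforms.
- Internal coordinates 0-based half-open; GFF3 read as 1-based closed and
  shifted; BED round-trips identically.
- The agglomeration is `stats::hclust`, which is deterministic for a fixed
  distance matrix; dendrograms are `stats::dendrogram` objects throughout,
  and Newick I/O reconstructs node heights as maximum distance-to-leaf.
- All randomness flows through integer seeds below 2³¹; `child_seed`
  derives per-stage streams.

## Known limitations

- Unshrunk per-gene dispersion (above): mild null anticonservativeness at
  small replicate counts.
- The published fold values appear truncated (3.56 printed as 3.5, 3.45 as
  3.4); `mitoarch` emits full precision and leaves rounding to presentation.
- A published worked example's p-value (3.90e-28) is not reproducible from
  its own printed counts, which give 5.78e-28 under any standard tail
  convention; the companion male value reproduces exactly under P(X ≥ k),
  which is the convention implemented. The acceptance suite records this
  discrepancy as a deliberately failing check rather than papering over it.
- The cluster-size window arithmetic sometimes quoted for max-gap clusters
  (a size-7 cluster spanning "up to 32 genes") is not consistent with the
  stated gap rule (7 members with six internal gaps of ≤ 5 span up to 37);
  the stated gap rule is what is implemented.
- `untangle_step2side`'s joint-escape phase is O(n²) per round and is
  skipped above `joint_max_leaves`; very large tanglegrams get the purely
  one-sided greedy.
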