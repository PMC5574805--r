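---
title: "Measuring phylogeny-function concordance with phylofunc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring phylogeny-function concordance with phylofunc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylofunc)
```

## The question and the model

A clade's ecology can track its history (niche conservatism: close
relatives fill similar roles) or escape it (adaptive radiation spreads close
relatives across niches; convergence pulls distant lineages into the same
niche). `phylofunc` asks, for a set of species with a rooted phylogeny and a
table of mixed-type functional traits, how concordant the phylogenetic and
functional structures are. No single statistic captures "concordance", so
the package follows a four-step design, each step probing a different
resolution:

1. pairwise distances (Mantel test between cophenetic and Gower matrices);
2. exact topologies (relative topological difference and branch score
   between the phylogeny and a functional dendrogram);
3. the heritability of a species' overall functional position
   (phylogenetic signal of a Brownian "functional identity");
4. per-species originality (correlation of evolutionary distinctiveness on
   the two trees).

A concordant system scores high on all four; the interesting biology lives
in the dissociations. Under Brownian trait evolution, for instance, pairwise
distances correlate strongly while exact topologies still differ almost
maximally — topology is a much finer object than a distance matrix, and the
RTD denominator counts every internal branch. The analysis drivers under
`analysis/` reproduce exactly this pattern on synthetic data.

## Functional dendrograms from mixed traits

Traits are typed (`quantitative`, `categorical`, `binary`) and grouped
(`habitat`, `trophic`, `behavior`); both mappings are data, supplied as a
YAML schema, never hard-coded. The Gower distance handles the mix: per
trait, quantitative contributions are `|x_i − x_j| / range` with the range
taken over the observed values of the table being analyzed (recomputed
after any subsetting, so every analysis is self-contained), discrete
contributions are 0/1 mismatch, and a trait with a missing value in either
species drops out of that pair's weighted mean. All traits carry equal
weight. Two degenerate cases are handled explicitly: a quantitative trait
with zero observed range is dropped with a warning (its contribution is
undefined), and a species pair sharing no observed trait is an error — the
pipeline pre-drops species greedily (most undefined pairs first) and logs
them in the model manifest, since group subtables under heavy missingness
can otherwise leave isolated pairs.

The dendrogram is agglomerative clustering of that matrix via
Lance-Williams updates (`stats::hclust` behind the `linkage()` surface).
Five methods are candidates — single, complete, UPGMA, WPGMA, Ward — and
the one whose cophenetic distances correlate best with the input wins;
ties go to the first method in that fixed order, so selection is
deterministic. "Ward" means the squared-distance `ward.D2` convention,
since the bare name is ambiguous. The dendrogram is exported as an
ultrametric rooted tree whose node heights are merge heights (half the
merge distance), making tip-to-tip cophenetic distance equal the
clustering's cophenetic distance and giving well-defined branch lengths
for normalization. Exact ties during agglomeration follow `hclust`'s
ordering; the test suite's independent naive oracle uses continuous random
matrices, where ties have probability zero.

## Comparing trees

Topological difference is the Robinson-Foulds symmetric difference of
non-trivial unrooted splits, canonicalized against a fixed reference tip.
RTD divides by `2n − 6`, the maximum for binary trees; with polytomies the
count uses the splits actually present while the denominator is kept as
printed, so RTD is conservative there (documented rather than redefined).
The branch score follows Kuhner-Felsenstein: over the union of splits of
both trees, including pendant branches, sum the squared differences of
branch lengths (zero where absent) — the square root is the headline value
and the squared sum is also exposed, because published values of this
statistic circulate in both conventions and on trees normalized to total
length 1 the sqrt form is bounded by √2 while the squared form is bounded
by 2. Both trees are normalized to total length 1 before scoring by
default, so trees in different units (substitutions vs. Gower heights) are
comparable. The two root-adjacent edges of a rooted tree map to one
unrooted branch; their lengths are summed, matching the usual unrooted
convention (and `phangorn::KF.dist`, against which the tests check).

## Phylogenetic signal of functional identity

A species' "place" in the functional tree is made quantitative by one
Brownian simulation along that tree: child state = parent state +
Normal(0, σ²·branch length), root 0. Moran's I of those tip values is then
computed on the *phylogeny*:

I = (n/S₀) Σ_{i≠j} w_ij z_i z_j / Σ z_i², z centred, S₀ = Σ w_ij.

The weights are where the two reported statistics differ: inverse
patristic distance (row-normalized) for Moran's I proper, and the Abouheif
proximity — 1 over the product of the direct-descendant counts of the
internal nodes on the path between two tips, a topology-only quantity —
for Abouheif's C_mean. Both matrices are pluggable. σ² is fixed at 1
because Moran's I is invariant to affine transformation of the values, so
the rate only rescales. Significance comes from permuting values over tips
(one-sided, greater; add-one p-value so p is never 0; exhaustive
enumeration available below n = 8 and verified against it). Because one
Brownian draw is a random realization, the default aggregates 100
replicates (mean statistic, per-replicate p-values, median p reported);
a single-replicate mode reproduces the one-draw protocol.

With equal weights I equals −1/(n−1) exactly — the classical null
expectation — which the tests assert to 1e−12; values under the
row-normalized proximities stay in [−1, 1] in practice but the bound is a
property of the weight spectrum, not enforced.

## Singularity

Fair-proportion evolutionary distinctiveness divides each branch length by
its number of descendant tips and credits it to each descendant; summing
over a species' ancestral branches gives its score, and the scores sum to
the total tree length exactly (a conservation law the tests check on 1,000
random trees, polytomies included). Computed on the phylogeny this is
phylogenetic singularity (PS), on the functional tree functional
singularity (FS); the two vectors are compared by a two-sided Pearson test
after label alignment. The supertree's root placement shifts individual ED
values, so a root edge, if present, is excluded by default
(`exclude_root_edge`). Quartile bins (ties to the lower bin, a constant
vector all in bin 1) support reporting and coloring.

## MRP supertrees

Source trees on overlapping taxon sets are combined by matrix
representation with parsimony: each internal clade of each source tree
becomes a binary character (members 1, other taxa of that tree 0, absent
taxa `?`), and a maximum-parsimony tree for the combined matrix is sought.
Scoring uses Hartigan's generalization of the Fitch pass — exact for
polytomies and for two-state characters — with `?` as an unconstrained
state, and is invariant to rooting. One convention matters enough to
stress: the analysis appends the standard hypothetical all-zero ancestor
before searching. Without it, clade characters from source trees with
missing taxa lose their grouping power entirely (two source trees
`((a,b),c)` and `((a,b),d)` leave all three 4-taxon topologies tied), a
fact easy to verify by exhaustive scoring; with it, shared clades are
recovered. The search uses stepwise random-addition starting trees (each
taxon inserted at its most parsimonious position, in random seeded order)
refined by NNI hill-climbing, best of `restarts` starts — adequate at the
scales this package targets (tens of taxa); no claim is made about
hundreds of taxa, where SPR/TBR searches in dedicated software are the
tool. MRP recovers topology only, so the returned tree carries unit branch
lengths and is rooted via the ancestor.

## The synthetic generator, and what it does not emulate

`simulate_yule_tree()` grows a pure-birth tree forward in time
(Exponential(k·λ) waits, uniform lineage choice) to n tips, extended to
the present, so trees are exactly ultrametric — a stand-in for the
clock-like, fully resolved phylogeny the analysis assumes.
`simulate_trait_table()` derives every trait from a latent Brownian
simulation on that tree, thresholded at the median for binary traits and
at empirical quantiles (3 levels by default) for categorical ones, so one
heritable process controls signal across all trait kinds. Three modes set
the evolutionary scenario: `conservative` keeps the Brownian values (niche
conservatism); `shuffled` permutes each trait independently across species
(no heritability — the type-I scenario); `convergent` draws an environment
grouping (3 groups by default) independently of the tree and sets trait
values to environment means plus small within-group noise (15% of the
Brownian tip scale), so distant lineages share states. Missingness is
injected per cell, independently, at a configurable rate, with at least
one fully observed species guaranteed by redrawing.

Real trait databases differ in ways the generator deliberately ignores:
missingness is structured by study effort rather than independent per
cell; traits are measured on wildly different scales with measurement
error; categorical codings are ordinal as often as nominal; and real
phylogenies carry polytomies and calibration uncertainty. Passing tests on
synthetic data therefore validate the *machinery* (every statistic, its
null distribution, its bookkeeping), not the field realism of any
particular dataset.

Default scales used by the test suite and the acceptance script — chosen
as a desk-scale working size for a study of this shape, and stated here as
the package's own choice: 50–60 species, 10 traits, 11% missingness (at
which roughly a third of species are fully observed), 999 permutations for
headline runs and 199 inside replicated power studies, 50–100 Brownian
replicates, 500 replicates for power/type-I rates.

## Numerical and design notes

* All label matching is by species name; positional alignment is never
  assumed, and mismatched sets are errors listing the offenders.
* Permutation p-values use the add-one convention and are reproducible
  bit-for-bit given (seed, n_perm); every pipeline stage derives its seed
  from the single run seed, so a config reproduces every number exactly.
* Missing branch lengths parse as 1 with a warning (topology-only newicks
  stay usable); negative lengths are rejected.
* The Mantel alternative is one-sided (greater) — concordance is a
  directional question; the Pearson singularity test is two-sided.
* Trait-pair screening picks its test from the kinds: Spearman
  (quant-quant), Cramér's V with chi-squared p (discrete-discrete),
  Kruskal-Wallis (quant-discrete); pairs with under 3 complete
  observations or a constant trait are reported untestable, not errors.
* Known limitations: the NNI+random-addition MP search is heuristic (no
  optimality guarantee); RTD's `2n−6` denominator under-normalizes for
  polytomous trees; Abouheif proximity construction is quadratic with an
  O(n) path walk per pair, fine to a few hundred tips.
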