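---
title: "Methods: joint mutational and transcriptional analysis of clonal evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint mutational and transcriptional analysis of clonal evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonepath)
```

## The problem

Full-length single-cell RNA-seq lets one call somatic point mutations and
measure gene expression in the same cells. After clonotyping (grouping
tumor cells by shared mutation profile) and expression clustering, each
cancer cell carries two labels — a clone and a transcriptional cluster —
and each clone carries a genotype over the called variant sites. clonepath
asks how gene programs change as clones evolve: which mutated or expressed
gene sets track the depth of a clone in the inferred evolutionary tree
(evolutionary path analysis), which track clone size (clonal selection
analysis), and whether those trends differ between clinical contexts such
as primary vs metastatic disease or drug response groups.

Upstream steps — variant calling, clonotyping, expression clustering, and
cell–cell interaction inference — are consumed as inputs, not performed
here. The package starts from a clone×site genotype matrix (values 0/1/2
for no mutation / heterozygous / homozygous, `NA` for missing), a cell
metadata table, optionally a normalized expression matrix, gene-set
collections (GMT), and a ligand–receptor interaction table.

## The clonal tree

Clones of one sample are ordered by a minimum spanning tree over pairwise
genotype distances. The distance is L1 over sites where both clones are
observed: the 0/1/2 coding orders heterozygous between wild-type and
homozygous, and L1 respects that ordering. A pair with no shared observed
site has undefined distance; if the remaining edges cannot span the clones
the tree is refused rather than guessed.

The MST is computed by Kruskal's algorithm with edges sorted by
(weight, lexicographic clone-id pair). Equal-weight spanning trees are
common on small genotype matrices, and this fixed tie-break makes the
output a deterministic function of the input — a property library MST
routines do not promise, which is why the package carries its own
~30-line implementation (validated in the test suite against brute-force
enumeration over all spanning trees).

The tree is rooted at the clone with the fewest mutated sites — the most
ancestral genotype under the infinite-sites intuition that mutations
accumulate. Ties go to the larger clone, then to the lexicographically
smaller id. Depth counts edges from the root. The root choice affects only
depths, never the edge set, and the edge set's invariance to row order and
cell counts is tested.

**Evolutionary paths.** One path per leaf, root to leaf. Clones with fewer
than `min_cells = 10` cells are removed from paths (their scores are too
noisy to rank reliably) but the tree is built from *all* clones, and
surviving clones keep their original depths: depth encodes distance from
the root, which filtering should not rescale. Whether small clones should
be dropped before or after tree construction is genuinely open; dropping
them only at path extraction preserves the topology information the small
clones carry. Paths retaining fewer than 3 clones are dropped — a
two-point rank correlation is ±1 by construction and pure noise.

## The scores

For a clone with mutated-gene set $M$ (any site with genotype ≥ 1; dosage
is not distinguished because all downstream scores operate on gene sets)
and a signature gene set $S$:

* **Mutation signature score** $M_s = |M \cap S| / |M \cup S|$, the
  Jaccard index, optionally after restricting both sets to a coding-gene
  (consensus CDS) filter so non-coding symbols cannot inflate the union.
  An empty union scores 0.
* **Transcription module score** $T_s$: per cell, the mean expression of
  the signature genes present in the matrix minus the mean of
  expression-matched controls. Genes are placed in `n_bins = 24`
  equal-frequency bins by average expression; each signature gene draws up
  to `n_ctrl = 100` control genes from its bin without replacement, capped
  at bin occupancy (tiny matrices therefore use the whole bin and are
  deterministic). Each signature gene's control draw is averaged
  separately and the draws are then averaged with equal weight; pooling
  the raw draws would weight cells by bin occupancy and introduce a small
  systematic bias whenever bins differ in size — the equal-weight form
  makes the expected score over random signatures exactly zero, a property
  the test suite checks by Monte Carlo. Control draws are seeded
  (default seed 0) and the seed is an explicit argument of every
  stochastic operation.
* **Mutated-gene expression score**: per cell, the mean expression over
  $M \cap S$ — the expression analogue of $M_s$, asking whether the
  mutated members of a program are actually transcribed. An empty
  intersection yields a missing value, never 0.
* **Mutated ligand–receptor score** $M_i$: interactions are inferred per
  transcriptional cluster, so each cluster/clone (the cells of one clone
  inside one cluster) faces the cancer-side gene set of its own cluster's
  interactions with a given partner cell type — ligand genes when the
  cancer cluster is the source, receptor genes when it is the target;
  complexes like `TGFBR1_TGFBR2` decompose into member genes. With
  $J_i$ the Jaccard between the clone's mutated genes and cluster $i$'s
  interaction set, $M_i = \sum_i n_i J_i / n_{clone}$, the
  cell-count-weighted mean. "Genes included in the interactions" is read
  as the cancer-side genes only; the directional readout (what the tumor
  emits vs displays) is the point of the score, and merging in
  partner-side genes would blur it.

KEGG-style metabolism sets are skipped when fewer than 3 signature genes
are shared with the expression matrix ($T_s$) or fewer than 3
intersecting genes are expressed (mutated-gene expression); cancer
signature sets are not subject to this rule. Per-clone values are the
mean over member cells; gene symbols are upper-cased at every ingest
point so GMT sets, genotype annotations and expression rownames cannot
disagree on case.

## The statistics

The **evolutionary path score** is the Spearman correlation (average
ranks) between per-clone scores and depth along one path; the **clonal
selection score** replaces depth with relative clone abundance (cell
count over the sample's cells, computed after the same < 10-cell
exclusion). At least 3 scored clones are required and zero-variance
scores give a missing value rather than 0 — an undefined rank correlation
is not evidence of no association.

**Cross-context comparison** pools coefficients by context — one
observation per path per sample for the path analysis (maximizing usable
observations; the sample-level alternative is a matter of aggregating
before pooling), one per sample for selection — and applies a two-sided
Wilcoxon rank-sum test for two contexts or Kruskal–Wallis for more.
Features passed in together form one Benjamini–Hochberg family; the
intended use is one family per score kind and comparison, matching how
result panels are reported separately. The significance threshold
defaults to q ≤ 0.1, and the context with the larger mean coefficient is
recorded as the enriched context so that "same-direction" overlaps are
computable.

For small pooled samples (n ≤ 12) the Wilcoxon p value is computed by
exact enumeration of the rank-sum permutation distribution with average
ranks. This stays exact under ties, which the classical exact
distribution does not handle — coefficient pools are full of tied ±1
values, where the normal approximation is at its worst. Larger pools use
the tie-corrected normal approximation.

**Overlap statistics.** Significant features from two analyses are
compared as feature-direction pairs (a feature enriched in different
contexts in the two analyses does not overlap). The total-overlap
statistic is observed/expected with observed $=|A\cap B|/U$ and expected
$=(|A|/U)(|B|/U)$; $U$ is the number of feature-direction pairs evaluated
in both analyses — "total" is read as total *tested*, not total
significant, since the expected-overlap formula is only a product of
independent rates under that reading (this is flagged here deliberately;
the alternative reading is not exposed). When either set is empty the
value is 0 by convention. The conditional variant divides the focal
group's overlap by its transcription-significant count, against the
same ratio over all groups, with zero denominators again yielding 0.

## Degeneracy

How strongly do clones prefer transcriptional states?

* **Normalized entropy**: Shannon entropy (base 2) of a clone's cluster
  occupancy divided by $\log_2 k$ for the sample's $k$ clusters; a clone
  occupying a single cluster is exactly 0, as is the degenerate $k=1$
  sample. The same per-cluster-over-clones statistic is reported
  symmetrically.
* **NMI**: mutual information between the clone and cluster partitions
  over $\sqrt{H(\text{clones})\,H(\text{clusters})}$, set to 0 when a
  marginal entropy is 0 (a single clone or cluster carries no
  information; this avoids 0/0). Base 2 throughout — normalization
  cancels the base for entropy but not for raw MI, so the base is fixed
  package-wide.
* **Simpson diversity** $1-\sum p_i^2$ over clone or cluster proportions.
* **Independence null**: within each sample, cluster labels are permuted
  across cells (clone labels fixed; permuting either side is equivalent
  in distribution, and fixing clones keeps clone-side statistics
  deterministic), the mean normalized clone entropy is recomputed per
  permutation, and a one-sided empirical p for observed < null is
  reported as $(1 + \#\{\text{null} \le \text{obs}\})/(n_{perm}+1)$,
  which can never report 0.

## The simulator

The simulator generates the conditions under which the path statistic is
validated, with defaults of 20 cells, 5 clones, 100 sites, FPR = FNR =
p.missing = 0.2, and 100 iterations. Topologies come from uniform
attachment (each new clone picks an existing parent uniformly), which
covers linear chains and stars without favoring either. Every non-root
clone receives at least one private mutation site — so all genotypes are
distinct and pairwise distances positive — and remaining sites are
assigned to originating clones uniformly, inherited by all descendants.
Cells are assigned uniformly with every clone guaranteed one cell.
Observation noise flips each entry independently (0→1 with FPR, 1→0 with
FNR) and then masks it with probability p.missing. One configuration seed
drives every draw; identical configs give identical reports.

Two stated noise defaults for the false-negative rate circulate in this
design's lineage (0.1 and 0.2); the package exposes both and defaults to
0.2, matching the explicit parameter listing rather than prose.

Reconstruction collapses cells to clone consensus genotypes by per-site
majority vote (ties vote mutated, biased toward detecting a mutation
that half the cells support; an all-missing site counts as unmutated)
and rebuilds the tree with the same MST machinery. The ground-truth
cell-to-clone assignment is reused deliberately: clustering is not the
component under test, and reusing the assignment isolates the path and
selection statistics from clustering error. A consequence is that clone
abundances are noise-free in selection mode, so the selection variant
validates the statistic's plumbing rather than its robustness.

With zero noise the reconstruction is provably exact: the L1 distance of
tree-inherited genotypes is additive along the true tree with strictly
positive edge weights, so every non-tree pair distance strictly exceeds
each edge on its path and the true tree is the *unique* MST. The test
suite asserts exact edge recovery over 20 seeds, and that a
depth-correlated "perfect" signature (value 1 + depth per clone) scores
exactly 1 on every reconstructed path while a random signature centers
at 0. The < 10-cell path filter is disabled in simulation mode: at 20
cells over 5 clones, average clone sizes of ~4 would empty every path.

## What the tests do and do not show

The synthetic generator emulates tree-structured genotypes with
independent per-entry observation noise and uniform cell assignment. It
does not emulate doublets, allele dropout correlated across sites,
copy-number effects on expression, clustering error (the true assignment
is reused), or expression matrices coupled to the genotypes. Passing
tests therefore demonstrate the statistics behave correctly on their
defined inputs, not that upstream clonotyping is reliable on real data.

Problem sizes in the test suite are chosen for exhaustive verifiability:
brute-force MST enumeration on up to 6 clones, exact rank-sum enumeration
up to pooled n = 12, permutation nulls at 999 permutations on 20-cell
toys, and the validation experiment at its default 100 iterations. These
sizes are where the oracles are exact; the implementation itself has no
size-dependent branches other than the documented exact/approximate
rank-sum switch.

## Known limitations

* The MST orders clones by genotype similarity; it is not a proper
  phylogenetic reconstruction and cannot place unobserved ancestors.
* Missing genotypes are treated as 0 when building mutated-gene sets
  (conservative; no imputation or genotype re-estimation is attempted).
* COSMIC-style membership in the per-clone summary is matched on
  caller-supplied variant identifiers; whether membership should be
  variant- or gene-level is left to the caller's set.
* Clone and cluster ids are sample-scoped semantically, but the clone ids
  in a genotype matrix must be globally unique strings (e.g., prefixed
  with the sample id); analyses never merge labels across samples.
* Tumor–tumor interactions can be scored by passing the merged
  interaction table, but are not a default.
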