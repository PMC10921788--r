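# clonepath

Joint analysis of the mutational and transcriptional landscapes of tumors
from full-length single-cell RNA-seq.

After upstream variant calling, clonotyping and expression clustering,
every cancer cell carries a clone label and a transcriptional cluster
label, and every clone carries a genotype over the called variant sites
(0/1/2 = none/het/hom, `NA` = missing). `clonepath` takes these inputs and
asks how gene programs change as clones evolve:

* **Clonal tree.** Clones of a sample are ordered by a minimum spanning
  tree over pairwise L1 genotype distances (deterministic Kruskal
  tie-break), rooted at the clone with the fewest mutated sites; depth
  counts edges from the root, and root-to-leaf paths are the evolutionary
  paths. Clones with fewer than 10 cells are dropped from paths (not from
  the tree), and paths keeping fewer than 3 clones are discarded.
* **Scores.** For a clone with mutated-gene set *M* and signature *S*:
  the mutation signature score *M*<sub>s</sub> = |M ∩ S| / |M ∪ S|
  (Jaccard, optional consensus-CDS filter); the transcription module
  score *T*<sub>s</sub> (per-cell signature mean minus expression-matched
  bin controls); the mutated-gene expression score (mean expression over
  M ∩ S); and the mutated ligand-receptor score
  *M*<sub>i</sub> = Σ<sub>i</sub> n<sub>i</sub>·J<sub>i</sub> / n<sub>clone</sub>,
  the cell-count-weighted mean over a clone's cluster/clones of the
  Jaccard between its mutated genes and the cancer-side genes of each
  cluster's interactions with a TME partner.
* **Statistics.** The evolutionary path score is the Spearman correlation
  of per-clone scores against depth along one path; the clonal selection
  score correlates scores with relative clone abundance. Coefficients are
  pooled by clinical context and compared by a two-sided Wilcoxon
  rank-sum test (exact under ties for small pools) or Kruskal–Wallis,
  with Benjamini–Hochberg correction per score kind (q ≤ 0.1 default),
  plus observed/expected overlap statistics between significant feature
  sets.
* **Degeneracy.** Normalized Shannon entropy of cluster occupancy per
  clone (0 for a single-cluster clone), sqrt-normalized mutual
  information, Simpson diversity, and a within-sample label-permutation
  null for clone–cluster independence.
* **Simulation.** A generator of ground-truth clonal trees with inherited
  mutations, per-entry genotype noise (FPR/FNR/missing), consensus-vote
  reconstruction, and a validation experiment comparing a depth-correlated
  "perfect" signature against a random one.

See the methods vignette (`vignettes/clonal-evolution-methods.Rmd`) for
the model, conventions, and design rationale.

## Worked example

A toy sample with four clones (genotype bitstrings over four annotated
sites) and 48 cells:

```r
library(clonepath)

g <- rbind("S1_cl1" = c(0L,0L,0L,0L), "S1_cl2" = c(1L,0L,0L,0L),
           "S1_cl3" = c(1L,1L,0L,0L), "S1_cl4" = c(0L,0L,0L,1L))
colnames(g) <- paste0("site", 1:4)
gm <- genotype_matrix(g, genes = c("EGFR", "KRAS", "TP53", "MET"))

sizes <- c(20, 12, 6, 10)
cells <- cell_table(data.frame(
  cell_id = paste0("c", 1:48), sample_id = "S1",
  clone_id = rep(paste0("S1_cl", 1:4), times = sizes),
  cluster_id = rep(c("x","x","y","y"), times = sizes)))

tree <- sample_trees(gm, cells)$S1
tree$nodes[, c("clone","n_cells","n_mutations","depth","parent")]
#>    clone n_cells n_mutations depth parent
#> 1 S1_cl1      20           0     0   <NA>
#> 2 S1_cl2      12           1     1 S1_cl1
#> 3 S1_cl3       6           2     2 S1_cl2
#> 4 S1_cl4      10           1     1 S1_cl1
```

The unmutated clone roots the tree; `S1_cl3` sits at depth 2 on the
EGFR→KRAS branch. Scoring against a receptor-tyrosine-kinase driver set
and correlating along paths (the 6-cell clone would be filtered at the
default `min_cells = 10`, so the toy lowers it):

```r
sets <- list(rtk_driver = c("EGFR","KRAS","MET"), tsg = c("TP53","RB1"))
st <- score_table(gm, cells, sets)
subset(st, feature == "rtk_driver")
#>  sample_id clone_id     kind    feature     score n_cells
#>         S1   S1_cl1 mutation rtk_driver 0.0000000      20
#>         S1   S1_cl2 mutation rtk_driver 0.3333333      12
#>         S1   S1_cl3 mutation rtk_driver 0.6666667       6
#>         S1   S1_cl4 mutation rtk_driver 0.3333333      10

path_result_table(subset(st, kind == "mutation"), tree,
                  min_cells = 5, sample_id = "S1")
#>  sample_id   path    feature rho n_clones
#>         S1 S1_cl3 rtk_driver   1        3
#>         S1 S1_cl3        tsg  NA        3

abundance_depth_correlation(tree)
#> [1] -0.9486833
```

Driver mutations accumulate monotonically along the surviving path
(ρ = 1); the tumor-suppressor set is unmutated everywhere, so its rank
correlation is undefined and reported missing rather than 0. Deeper
clones are smaller here (abundance–depth ρ ≈ −0.95). Clone–cluster
degeneracy for the same sample:

```r
as.data.frame(degeneracy_report(cells))[,
  c("n_clones","n_clusters","clone_entropy","nmi","simpson_clones")]
#>  n_clones n_clusters clone_entropy      nmi simpson_clones
#>         4          2             0 0.700251      0.7048611
```

Every clone occupies a single cluster (entropy 0) and the two labelings
share most of their information (NMI 0.70). Finally, the simulation-based
validation of the path statistic at its default noise settings:

```r
validation_experiment(sim_config(seed = 1L))
#> validation_report (path): 100 iterations
#>   perfect pool: n=155, median=1.000
#>   random pool:  n=155, median=0.500
#>   two-sided rank-sum p = 2.15e-30
```

A depth-correlated signature is cleanly separated from a random one even
at 20% false-positive/false-negative genotype noise with 20% missing
entries.

A command-line wrapper is installed as `exec/clonepath` with subcommands
`tree`, `score`, `path`, `selection`, `degeneracy`, `compare`, `overlap`
and `simulate`; every run writes a `manifest.json` with parameters and
input checksums.

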