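---
title: "Assigning polyploid alleles to diploid subgenomes by minimizing deep coalescences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning polyploid alleles to diploid subgenomes by minimizing deep coalescences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copolphase)
library(ape)
```

## The problem

Multi-locus phylogenetics of an allopolyploid is complicated by a missing
piece of information: each allele sampled from the polyploid belongs to one
of its diploid-derived subgenomes, but sequencing does not reveal which.
If that assignment were known, the polyploid could be split into
pseudo-diploid taxa and analysed with ordinary species-tree methods.

`copolphase` treats the assignment as an optimization variable. Given

* rooted gene trees for one or more loci (optionally many trees per locus,
  e.g. a posterior sample),
* an accession table mapping alleles to accessions, taxa and ploidy levels,

it searches for the partition of the focal polyploid's alleles into at most
$n/2$ subgenomes ($n$ = ploidy) that minimizes the number of extra lineages
— deep coalescences — in the optimal species tree over the diploid taxa plus
subgenome pseudo-taxa $P_1, \dots, P_k$. This is the minimizing-deep-
coalescences (MDC) parsimony criterion: discordance between gene trees and
a candidate species tree is priced in extra lineages, and a good allele
partition is one whose implied species tree needs few of them.

One biological constraint is enforced throughout: assuming single-copy loci
and disomic inheritance, an accession can contribute at most two alleles per
locus to any one subgenome. Partitions violating this are never generated
or visited.

## Scoring: extra lineages and MDC species trees

For a rooted gene tree embedded in a rooted species tree under an
allele-to-taxon mapping, the number of lineages exiting a species-tree
branch with taxon cluster $C$ equals the number of maximal gene-tree clades
whose leaves all map into $C$; the branch contributes (lineages − 1) extra
lineages, and the tree's cost is the sum over all branches below the root.
This cluster formulation equals the minimum over all valid coalescent
embeddings; the test suite verifies that equivalence against a brute-force
enumerator of embeddings on all small instances. Multifurcations in gene
trees are treated as soft polytomies: counting maximal clades on the
multifurcating tree directly never charges an unresolved posterior tree for
resolutions it does not assert.

Scores for a gene tree set are summed over **all** trees of **all** loci,
with no per-locus averaging, so a locus represented by a larger posterior
sample carries proportionally more weight.

Species-tree inference offers two modes:

* `exhaustive` enumerates every rooted binary topology (at most 9 taxa) —
  kept mainly as an oracle for tests;
* `clusters` (default) is a dynamic program over taxon subsets. For up to
  12 taxa it runs over *all* subsets and is therefore exact — equivalent to
  exhaustive enumeration at polynomial cost per gene tree. Beyond 12 taxa
  it restricts candidate clusters to those induced by the gene trees, their
  complements and singletons, which recovers the optimum whenever the
  optimal tree's clusters appear among the candidates.

Ties between equally parsimonious species trees are broken toward the
lexicographically smallest canonical (sorted) Newick string, so results are
reproducible across runs and platforms.

## The tabu search

The number of valid partitions grows exponentially with loci (a tetraploid
with four alleles at each of $L$ loci admits $6^L$ locus-wise pairings), so
the partition is optimized by tabu search:

* **Moves.** SHIFT reassigns one allele to a subgenome with free capacity;
  SWAP exchanges the subgenomes of two same-accession, same-locus alleles.
  Swaps are essential: at a saturated tetraploid locus (4 alleles, $k = 2$)
  no shift preserves validity, and a wrong pairing is exactly one swap away
  from the correct one.
* **Tabu attribute.** Applying a move forbids, for `tabu_tenure`
  iterations, re-placing each moved allele into the subgenome it just left.
  A tabu move is still admissible if it improves on the best score found so
  far (aspiration).
* **Sampling.** Each iteration draws up to `neighborhood_sample_size`
  moves uniformly without replacement, scores them, and applies the best
  admissible one — evaluating a batched sample rather than the full
  neighborhood trades per-iteration quality for many more iterations per
  unit time.
* **Restarts** rerun the search from fresh uniform random partitions; the
  best solution across restarts is reported.

Random starting partitions are drawn uniformly among capacity-respecting
assignments, independently per accession-locus group (exact enumeration of
the valid assignments of each group, then a uniform draw). Scores are
cached under a canonical form of the partition that quotients out the $k!$
subgenome-label symmetry, since species-tree inference dominates the cost
of every evaluation.

Defaults (`tabu_params()`): tenure 5, 60 iterations, sample size 25, one
restart. They were chosen from the structure of the search space — with 20
tetraploid loci a random start has roughly two-thirds of its loci
mispaired, each fixable by one of two specific swaps among the four at that
locus, so 60 iterations at sample size 25 give each needed swap many
chances to be drawn. Tenure is deliberately short; the landscape's
local optima are shallow at this scale. As the number of loci or the
ploidy grows, `max_iterations` should grow roughly linearly with the
number of mispaired loci; testing a few tenure values is advisable since
no single default suits all datasets.

## Combining replicate reconstructions

Repeated runs may end in different local optima, and even identical
partitions come back with arbitrary subgenome labels. Each run's partition
is written as a binary membership matrix (rows = alleles, columns =
subgenomes, one 1 per row). Columns are aligned across runs by minimizing
the mean Shannon entropy of the averaged coefficients,
$$\bar H = \frac1N \sum_i \Big( -\sum_j c_{ij} \log c_{ij} \Big), \qquad 0 \log 0 := 0,$$
with natural logarithm — the base only rescales the objective and cannot
change the argmin. Zero mean entropy means the aligned replicates agree
perfectly.

The first replicate's permutation is pinned to the identity because a
common permutation of all replicates leaves $\bar H$ unchanged ($C!$
equivalent optima otherwise); remaining ties are broken toward the
lexicographically smallest permutation tuple. `exact` mode enumerates all
$(C!)^{K-1}$ alignments and is used in tests; `iterative` mode (default)
cycles over replicates re-optimizing one permutation at a time until no
improvement, with random restarts, and matches the exact optimum on every
enumerable instance we test. The aligned permutations can then be applied
to the species trees' pseudo-taxon leaves (`relabel_trees()`), after which
an ordinary greedy consensus (`greedy_consensus()`, clades added in order
of decreasing frequency while compatible, optionally thresholded at 0.5)
summarizes the replicate topologies.

## The simulation harness

`run_validation()` reproduces the validation design at configurable scale:

1. **Species trees.** Pure-birth (Yule) trees with uniform speciation rate,
   rescaled to a fixed root-to-tip depth; defaults are 8 taxa and a depth
   of $10^6$ generations.
2. **Gene trees.** Multispecies-coalescent simulation inside the species
   tree with two alleles per taxon and $N_e = 10^5$ by default. $N_e$ is
   interpreted as the number of diploid individuals: pairwise coalescence
   rate $1/(2N_e)$ per generation. (The alternative convention differs by a
   factor of two; the test suite pins ours via the small-$N_e$ concordance
   limit.) With these defaults internal branches span roughly 0.2–5
   coalescent units, i.e. a considerable amount of incomplete lineage
   sorting.
3. **Artificial polyploids.** Two (tetraploid) or three (hexaploid) taxa
   are merged into one accession whose alleles become the partition
   variables; the allele-to-source-taxon map is kept as ground truth.
   Allele identifiers are locus-qualified, so nothing links alleles across
   loci — exactly the information the method is supposed to reconstruct.
   When the merge is drawn at random, sets that are monophyletic in the
   species tree are excluded: a polyploid whose complete parental clade was
   removed from the diploid pool is the autopolyploid-like corner case in
   which subgenome identity is close to undefined, whereas the target model
   is an allopolyploid with distinct parental lineages. Explicit merge
   lists may still request monophyletic sets.
4. **Evaluation.** Reconstructions are scored by (a) the normalized
   Robinson–Foulds distance between the inferred species tree and the
   truth, minimized over the $k!$ subgenome-to-taxon bijections, and (b)
   the fraction of alleles assigned to their true source taxon, again
   maximized over bijections. RF is computed on unrooted topologies and
   normalized by $2(n-3)$; for 8-leaf trees it can only attain
   $\{0, 0.2, 0.4, 0.6, 0.8, 1\}$. A diploid-only MDC species tree from
   the same loci (true allele-to-taxon mapping, no polyploid) serves as
   the baseline that isolates the cost of not knowing the subgenome
   memberships.

The default configuration is the full-scale grid (30 species trees, pools
of 10,000 gene trees, subsets of 2/5/10/20 loci, 24 replicates per
constellation); tests and the acceptance script run a scaled-down grid
(3 species trees, pools of 60 gene trees, 20 loci, 3 replicates — chosen
as the smallest batch in which every component is exercised end to end and
means are stable across seeds).

What the simulation does *not* emulate: gene-tree estimation error (trees
are simulated, not inferred from sequences), recombination between
subgenomes, polysomic or mixed inheritance, and allele sampling failure
(every taxon contributes exactly two alleles per locus). Passing the
validation therefore shows that the optimizer and scoring machinery recover
subgenomes under clean disomic inheritance and known gene trees, not that
they are robust to violations of those assumptions on real data.

## A small worked example

```{r example}
## an allotetraploid X whose alleles x1/x2 track taxon A and x3/x4 taxon B
tab <- accession_table(do.call(rbind, lapply(c("L1", "L2"), function(lc) rbind(
  data.frame(accession = "accA", taxon = "A", ploidy = 2, locus = lc,
             alleles = paste0("a1_", lc, ",a2_", lc)),
  data.frame(accession = "accB", taxon = "B", ploidy = 2, locus = lc,
             alleles = paste0("b1_", lc, ",b2_", lc)),
  data.frame(accession = "accC", taxon = "C", ploidy = 2, locus = lc,
             alleles = paste0("c1_", lc, ",c2_", lc)),
  data.frame(accession = "accX", taxon = "X", ploidy = 4, locus = lc,
             alleles = paste0("x1_", lc, ",x2_", lc, ",x3_", lc, ",x4_", lc))))))
gts <- gene_tree_set(lapply(setNames(nm = c("L1", "L2")), function(lc) {
  s <- function(x) paste0(x, "_", lc)
  read.tree(text = sprintf(
    "((((%s,%s),(%s,%s)),((%s,%s),(%s,%s))),(%s,%s));",
    s("a1"), s("a2"), s("x1"), s("x2"),
    s("b1"), s("b2"), s("x3"), s("x4"), s("c1"), s("c2")))
}))

res <- tabu_search(gts, tab, "X", params = tabu_params(rng_seed = 1))
res$best_score$total
table(res$best_partition$assignment[paste0("x", 1:4, "_L1")])
write.tree(res$best_tree)
```

The search separates the A-like from the B-like alleles and places the two
subgenome pseudo-taxa as sisters of their source lineages at zero extra
lineages.

## Numerical and degenerate-input choices

* Taxon sets are encoded as 32-bit masks; at most 30 taxa per analysis.
* Fewer than three mapped taxa yield the trivial species tree with a
  warning rather than an error.
* Clusters with no sampled alleles in some gene tree contribute
  $\max(k-1, 0) = 0$ extra lineages, so incompletely sampled loci are
  never charged for taxa they do not contain.
* Unrooted gene trees (basal polytomy) are rejected at parse time instead
  of being silently rooted; internal polytomies are accepted as soft.
* Branch lengths are parsed but ignored by scoring — MDC is topology-only.
* All stochastic components (simulation, tabu search, alignment restarts)
  take explicit integer seeds, and per-replicate seeds in
  `run_validation()` derive deterministically from one master seed.

## Known limitations

* One focal polyploid per run; datasets with several polyploids are
  handled by sequential runs, pruning the others' alleles each time.
* The candidate-restricted dynamic program above 12 taxa is heuristic:
  optimality is guaranteed only when the optimal tree's clusters appear in
  the gene trees.
* Entropy alignment assumes a hidden one-to-one correspondence of
  subgenomes across replicates; it cannot detect that replicates disagree
  qualitatively (e.g. an autopolyploid without separable subgenomes) —
  averaged coefficients near $1/k$ are the signal to look for.
* Accuracy figures from the simulation transfer to real data only to the
  extent that the simulation's assumptions (known rooted gene trees,
  strict disomy, complete sampling) hold.
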