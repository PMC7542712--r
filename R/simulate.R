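## Validation machinery: Yule species trees, multispecies-coalescent gene
## trees, artificial allopolyploids, and Robinson-Foulds evaluation.

#' Simulate a Yule (pure-birth) species tree
#'
#' Uniform-rate pure-birth tree on `n_taxa` leaves whose edge lengths are
#' rescaled so the root-to-tip depth equals `depth` generations. Tips are
#' labelled `T1..Tn`.
#'
#' @param n_taxa Number of leaves (>= 3).
#' @param depth Total tree depth in generations after rescaling.
#' @param seed Optional integer seed.
#' @return Rooted ultrametric `phylo` with branch lengths in generations.
#' @export
simulate_yule_tree <- function(n_taxa, depth = 1e6, seed = NULL) {
  if (!is_count(n_taxa) || n_taxa < 3L) copol_stop("n_taxa must be an integer >= 3")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  cur <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (depth / cur)
  tr$tip.label <- paste0("T", seq_len(n_taxa))
  tr
}

## heights (time before present) of all nodes of an ultrametric tree
node_heights <- function(tr) {
  d <- ape::node.depth.edgelength(tr)
  max(d) - d
}

#' Simulate coalescent gene trees within a species tree
#'
#' Standard multispecies coalescent: each taxon contributes
#' `alleles_per_taxon` lineages at the present; within every species-tree
#' branch, lineage pairs coalesce at rate 1/(2*Ne) per generation (Ne =
#' number of diploid individuals); lineages that fail to coalesce are passed
#' to the ancestral branch, and remaining lineages coalesce above the root.
#' Leaves of locus `Lxx` are labelled `taxon_alleleIdx_Lxx`, so allele
#' identifiers are unique per locus (homology of alleles across loci is not
#' assumed known).
#'
#' @param species_tree Rooted ultrametric `phylo`, branch lengths in
#'   generations.
#' @param Ne Effective population size (diploid individuals).
#' @param n_trees Number of gene trees (one locus each).
#' @param alleles_per_taxon Lineages sampled per taxon.
#' @param seed Optional integer seed.
#' @param locus_prefix Prefix for locus identifiers.
#' @return A `gene_tree_set` with `n_trees` loci of one tree each.
#' @export
simulate_gene_trees <- function(species_tree, Ne = 1e5, n_trees,
                                alleles_per_taxon = 2L, seed = NULL,
                                locus_prefix = "L") {
  if (!is.null(seed)) set.seed(seed)
  if (!is_count(n_trees)) copol_stop("n_trees must be a positive integer")
  h <- node_heights(species_tree)
  ntip <- ape::Ntip(species_tree)
  root <- ntip + 1L
  kids <- split(species_tree$edge[, 2L], species_tree$edge[, 1L])
  width <- max(2L, nchar(as.character(n_trees)))
  loci <- sprintf("%s%0*d", locus_prefix, width, seq_len(n_trees))
  trees <- lapply(loci, function(locus) {
    msc_one_tree(species_tree, h, ntip, root, kids, Ne, alleles_per_taxon, locus)
  })
  names(trees) <- loci
  gene_tree_set(trees)
}

## one coalescent gene tree; lineages carry (newick fragment, height)
msc_one_tree <- function(st, h, ntip, root, kids, Ne, apt, locus) {
  rate2 <- 1 / (2 * Ne)     # pairwise coalescence rate per generation
  coalesce_in <- function(pool, t0, t1) {
    t <- t0
    while (length(pool$frag) >= 2L) {
      k <- length(pool$frag)
      wait <- stats::rexp(1L, rate = k * (k - 1) / 2 * rate2)
      if (t + wait > t1) break
      t <- t + wait
      ij <- sample.int(k, 2L)
      i <- ij[1L]; j <- ij[2L]
      frag <- paste0("(", pool$frag[i], ":", t - pool$height[i], ",",
                     pool$frag[j], ":", t - pool$height[j], ")")
      pool$frag <- c(pool$frag[-c(i, j)], frag)
      pool$height <- c(pool$height[-c(i, j)], t)
    }
    pool
  }
  pools <- vector("list", ntip + st$Nnode)
  ## process nodes by increasing height: tips first, then internals
  ord <- order(h[(ntip + 1L):(ntip + st$Nnode)]) + ntip
  for (tip in seq_len(ntip)) {
    labs <- paste0(st$tip.label[tip], "_", seq_len(apt), "_", locus)
    pools[[tip]] <- list(frag = labs, height = rep(0, apt))
  }
  parent_of <- integer(ntip + st$Nnode)
  parent_of[st$edge[, 2L]] <- st$edge[, 1L]
  for (tip in seq_len(ntip)) {
    p <- parent_of[tip]
    surv <- coalesce_in(pools[[tip]], h[tip], h[p])
    pools[[p]] <- merge_pools(pools[[p]], surv)
  }
  for (nd in ord) {
    if (nd == root) next
    p <- parent_of[nd]
    surv <- coalesce_in(pools[[nd]], h[nd], h[p])
    pools[[p]] <- merge_pools(pools[[p]], surv)
  }
  final <- coalesce_in(pools[[root]], h[root], Inf)
  ape::read.tree(text = paste0(final$frag[1L], ";"))
}

merge_pools <- function(a, b) {
  if (is.null(a)) return(b)
  list(frag = c(a$frag, b$frag), height = c(a$height, b$height))
}

#' Merge diploid taxa into an artificial polyploid
#'
#' Treats 2 (tetraploid) or 3 (hexaploid) diploid taxa as subgenomes of a
#' hypothetical allopolyploid: their alleles are combined into one accession
#' of ploidy 2 x |merged_taxa| under `polyploid_label`. Gene-tree topologies
#' are untouched; the true allele-to-source-taxon map is returned as ground
#' truth.
#'
#' @param gts A `gene_tree_set`.
#' @param tab An `accession_table` of the diploid taxa.
#' @param merged_taxa Character vector of 2 or 3 diploid taxon labels.
#' @param polyploid_label Taxon label of the artificial polyploid.
#' @return List with `gts` (unchanged), `tab` (new `accession_table`) and
#'   `truth` (named character vector: allele -> source taxon).
#' @export
make_polyploid <- function(gts, tab, merged_taxa, polyploid_label) {
  if (!length(merged_taxa) %in% c(2L, 3L)) {
    copol_stop("merged_taxa must contain 2 or 3 taxa")
  }
  if (anyDuplicated(merged_taxa)) copol_stop("merged_taxa must be distinct")
  ttab <- tab$alleles
  if (!all(merged_taxa %in% ttab$taxon)) {
    copol_stop("merged taxon absent from the accession table")
  }
  remaining <- setdiff(unique(ttab$taxon), merged_taxa)
  if (polyploid_label %in% remaining) {
    copol_stop("polyploid_label collides with a remaining diploid taxon")
  }
  rec <- tab$records
  merged_rows <- rec$taxon %in% merged_taxa
  keep <- rec[!merged_rows, , drop = FALSE]
  ml <- ttab[ttab$taxon %in% merged_taxa, , drop = FALSE]
  ploidy <- 2L * length(merged_taxa)
  poly <- do.call(rbind, lapply(sort(unique(ml$locus)), function(lc) {
    data.frame(accession = paste0(polyploid_label, "_1"),
               taxon = polyploid_label, ploidy = ploidy, locus = lc,
               alleles = paste(sort(ml$allele[ml$locus == lc]), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  truth <- stats::setNames(ml$taxon, ml$allele)
  list(gts = gts, tab = accession_table(rbind(keep, poly)), truth = truth)
}

#' Normalized Robinson-Foulds distance between unrooted topologies
#'
#' Symmetric difference of the non-trivial bipartitions of the two unrooted
#' topologies, divided by the maximum 2(n-3). For fully resolved 8-leaf
#' trees, only the values 0, 0.2, 0.4, 0.6, 0.8, 1 can occur.
#'
#' @param tree_a,tree_b `phylo` trees with identical leaf sets of >= 4 leaves.
#' @return Number in [0, 1].
#' @export
normalized_rf <- function(tree_a, tree_b) {
  if (!identical(sort(tree_a$tip.label), sort(tree_b$tip.label))) {
    copol_stop("trees must share an identical leaf set")
  }
  if (ape::Ntip(tree_a) < 4L) copol_stop("at least 4 leaves required")
  ua <- ape::unroot(tree_a); ub <- ape::unroot(tree_b)
  as.numeric(phangorn::RF.dist(ua, ub, normalize = TRUE, check.labels = TRUE))
}

#' Candidate subgenome-to-taxon mappings
#' @param merged_taxa Taxa merged into the polyploid.
#' @return List of named character vectors `P1..Pk` -> taxon (k! entries).
#' @export
subgenome_mappings <- function(merged_taxa) {
  k <- length(merged_taxa)
  lapply(permutations(k), function(p) {
    stats::setNames(merged_taxa[p], paste0("P", seq_len(k)))
  })
}

#' Best-mapping normalized RF distance
#'
#' A reconstructed species tree carries anonymous subgenome leaves `P1..Pk`;
#' each of the k! bijections to the true merged taxa yields one candidate
#' relabelling, and the minimum normalized RF distance to the true species
#' tree over all of them is returned (2 candidates for a tetraploid, 6 for a
#' hexaploid).
#'
#' @param inferred Rooted `phylo` with pseudo-taxon leaves `P1..Pk`.
#' @param true_tree `phylo` over the diploid taxa (including `merged_taxa`).
#' @param merged_taxa The k taxa merged into the polyploid.
#' @param details If `TRUE`, also return all candidate distances.
#' @return Minimum normalized RF (or a list when `details = TRUE`).
#' @export
best_mapping_rf <- function(inferred, true_tree, merged_taxa, details = FALSE) {
  k <- length(merged_taxa)
  plabs <- paste0("P", seq_len(k))
  if (!all(plabs %in% inferred$tip.label)) {
    copol_stop("inferred tree must contain pseudo-taxa ", paste(plabs, collapse = ", "))
  }
  maps <- subgenome_mappings(merged_taxa)
  dists <- vapply(maps, function(mp) {
    tr <- inferred
    idx <- match(plabs, tr$tip.label)
    tr$tip.label[idx] <- unname(mp[plabs])
    normalized_rf(tr, true_tree)
  }, 0)
  if (details) list(rf = min(dists), candidates = dists, mappings = maps)
  else min(dists)
}

#' Agreement of an inferred partition with the true allele origins
#'
#' Subgenome labels are arbitrary, so the fraction of correctly assigned
#' alleles is maximized over all bijections between subgenomes and source
#' taxa.
#'
#' @param partition An `allele_partition` over the polyploid's alleles.
#' @param truth Named character vector: allele -> true source taxon.
#' @param merged_taxa The candidate source taxa (defaults to the distinct
#'   values of `truth`); must have length `partition$k`.
#' @return Fraction in [0, 1].
#' @export
partition_accuracy <- function(partition, truth, merged_taxa = sort(unique(truth))) {
  alleles <- names(partition$assignment)
  if (!all(alleles %in% names(truth))) copol_stop("truth does not cover all alleles")
  k <- partition$k
  if (length(merged_taxa) != k) copol_stop("subgenome count differs from taxon count")
  best <- 0
  for (p in permutations(k)) {
    lab <- merged_taxa[p][partition$assignment[alleles]]
    best <- max(best, mean(lab == truth[alleles]))
  }
  best
}

#' Simulation configuration
#'
#' Defaults follow the validation design: 8-taxon Yule trees of depth 10^6
#' generations, Ne = 10^5, two alleles per taxon, a pool of 10,000 gene
#' trees per species tree, loci subsets of size 2/5/10/20 and 24 replicates
#' per constellation over 30 species trees. Scale down `n_species_trees`,
#' `n_gene_trees`, `loci_subset_sizes` and `replicates` for desk-size runs.
#'
#' @param n_taxa,tree_depth,Ne,alleles_per_taxon Coalescent parameters.
#' @param n_species_trees Number of independent Yule species trees.
#' @param n_gene_trees Size of the simulated gene-tree pool per species tree.
#' @param merges Either `"tetraploid"`/`"hexaploid"` (one random merge of
#'   non-monophyletic taxa per species tree, emulating an allopolyploid whose
#'   subgenomes trace to distinct parental lineages) or a list of character
#'   vectors of taxa to merge (which may include monophyletic sets).
#' @param loci_subset_sizes Numbers of loci drawn per reconstruction.
#' @param replicates Reconstructions per constellation.
#' @param tabu A [tabu_params()] object for the reconstructions.
#' @param rng_seed Master seed; all per-replicate seeds derive from it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa = 8L, tree_depth = 1e6, Ne = 1e5,
                              alleles_per_taxon = 2L, n_species_trees = 30L,
                              n_gene_trees = 10000L, merges = "tetraploid",
                              loci_subset_sizes = c(2L, 5L, 10L, 20L),
                              replicates = 24L, tabu = tabu_params(),
                              rng_seed = 1L) {
  structure(list(n_taxa = n_taxa, tree_depth = tree_depth, Ne = Ne,
                 alleles_per_taxon = alleles_per_taxon,
                 n_species_trees = n_species_trees,
                 n_gene_trees = n_gene_trees, merges = merges,
                 loci_subset_sizes = loci_subset_sizes,
                 replicates = replicates, tabu = tabu,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

## diploid accession table for a simulated gene tree set: one accession per
## taxon, ploidy 2, locus-qualified allele names
diploid_table <- function(gts, taxa, alleles_per_taxon) {
  rows <- do.call(rbind, lapply(gts$loci, function(lc) {
    labs <- gts$trees[[lc]][[1]]$tip.label
    do.call(rbind, lapply(taxa, function(tx) {
      al <- labs[startsWith(labs, paste0(tx, "_"))]
      data.frame(accession = paste0(tx, "_1"), taxon = tx, ploidy = 2L,
                 locus = lc, alleles = paste(sort(al), collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }))
  accession_table(rows)
}

#' Run the simulation-based validation loop
#'
#' For each simulated species tree: draw a pool of coalescent gene trees,
#' merge the configured taxa into an artificial polyploid, and for each loci
#' subset size and replicate (a) reconstruct the allele partition and species
#' tree by tabu search and (b) compute the diploid-only MDC species tree from
#' the same loci as a baseline. Each reconstruction is scored by the
#' normalized RF distance to the true species tree (best subgenome mapping
#' for the polyploid) and by the allele-assignment accuracy.
#'
#' @param config A [simulation_config()].
#' @return List with `records` (one row per replicate: species_tree, merge,
#'   n_loci, replicate, rf_polyploid, rf_diploid, accuracy, score) and
#'   `summary` (means by n_loci), plus `failed` (count of skipped
#'   replicates).
#' @export
run_validation <- function(config) {
  seeds <- seed_stream(config$rng_seed, 10000L)
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    seeds[si]
  }
  records <- list()
  failed <- 0L
  for (s in seq_len(config$n_species_trees)) {
    st <- simulate_yule_tree(config$n_taxa, config$tree_depth, seed = next_seed())
    pool <- simulate_gene_trees(st, Ne = config$Ne, n_trees = config$n_gene_trees,
                                alleles_per_taxon = config$alleles_per_taxon,
                                seed = next_seed())
    taxa <- st$tip.label
    merges <- if (is.list(config$merges)) config$merges else {
      m <- if (identical(config$merges, "hexaploid")) 3L else 2L
      set.seed(next_seed())
      ## merged subgenomes must trace to distinct parental lineages: reject
      ## merges that are monophyletic in the species tree (a polyploid whose
      ## ancestors form a clade is indistinguishable from an autopolyploid)
      repeat {
        cand <- sort(sample(taxa, m))
        if (!ape::is.monophyletic(st, cand)) break
      }
      list(cand)
    }
    tab0 <- diploid_table(pool, taxa, config$alleles_per_taxon)
    for (merge in merges) {
      mk <- make_polyploid(pool, tab0, merge, "POLY")
      for (L in config$loci_subset_sizes) {
        for (rep_i in seq_len(config$replicates)) {
          seed_r <- next_seed()
          rec <- tryCatch(
            validate_once(st, pool, tab0, mk, merge, L, config, seed_r),
            copol_error = function(e) NULL, error = function(e) NULL)
          if (is.null(rec)) {
            failed <- failed + 1L
            next
          }
          rec$species_tree <- s
          rec$merge <- paste(merge, collapse = "+")
          rec$n_loci <- L
          rec$replicate <- rep_i
          records[[length(records) + 1L]] <- rec
        }
      }
    }
  }
  records <- do.call(rbind, records)
  summary <- if (!is.null(records)) {
    stats::aggregate(records[c("rf_polyploid", "rf_diploid", "accuracy")],
                     by = records["n_loci"], FUN = mean)
  } else NULL
  list(records = records, summary = summary, failed = failed)
}

validate_once <- function(st, pool, tab0, mk, merge, L, config, seed_r) {
  set.seed(seed_r)
  loci <- sort(sample(pool$loci, L))
  sub <- gene_tree_set(mk$gts$trees[loci])
  tp <- config$tabu
  tp$rng_seed <- seed_r
  res <- tabu_search(sub, mk$tab, "POLY", params = tp)
  rf_poly <- best_mapping_rf(res$best_tree, st, merge)
  acc <- partition_accuracy(res$best_partition, mk$truth, sort(merge))
  ## diploid-only baseline on the same loci
  dip_map <- stats::setNames(tab0$alleles$taxon, tab0$alleles$allele)
  base <- infer_mdc_tree(gene_tree_set(pool$trees[loci]), dip_map, mode = "clusters")
  rf_dip <- normalized_rf(base$tree, st)
  data.frame(rf_polyploid = rf_poly, rf_diploid = rf_dip, accuracy = acc,
             score = res$best_score$total)
}
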