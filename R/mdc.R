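## Minimizing-deep-coalescences engine: extra-lineage counting and
## MDC-optimal species tree inference.
##
## Counting uses the standard cluster formulation: for a species-tree branch
## whose taxon cluster is C, the number of lineages exiting the branch equals
## the number of maximal gene-tree clades whose leaves all map into C; the
## branch contributes max(k - 1, 0) extra lineages. Gene-tree polytomies are
## treated as soft (children may be counted as already coalesced), which is
## the optimistic reading appropriate for unresolved consensus trees.
## Taxon sets are encoded as 32-bit bitmasks, so at most 30 taxa per analysis.

MAX_TAXA <- 30L

## ---- scoring context -------------------------------------------------------

## Topology skeleton of one tree (postorder edges, parent pointers); computed
## once and reused across scoring calls with different mappings.
tree_skeleton <- function(tr) {
  ntip <- ape::Ntip(tr)
  nn <- ntip + tr$Nnode
  trp <- stats::reorder(tr, "postorder")
  e <- trp$edge
  par <- integer(nn)
  par[e[, 2L]] <- e[, 1L]
  root <- e[nrow(e), 1L]
  par[root] <- 0L
  list(ntip = ntip, nn = nn, edge = e, parent = par, tip.label = tr$tip.label)
}

skeletons_of <- function(trees) lapply(trees, tree_skeleton)

## Precompute, for a set of gene trees under a leaf -> taxon mapping, flat
## per-node arrays: taxon bitmask below each node, parent index, tree id.
## A sentinel node with mask -1 acts as "parent" of every root so that a
## root always counts as a maximal clade when its mask fits the cluster.
mdc_context <- function(trees, mapping, taxa = NULL, skeletons = NULL) {
  if (is.null(taxa)) taxa <- sort(unique(unname(mapping)))
  if (length(taxa) > MAX_TAXA) copol_stop("at most ", MAX_TAXA, " taxa supported")
  if (is.null(skeletons)) skeletons <- skeletons_of(trees)
  taxon_bit <- stats::setNames(bitwShiftL(1L, seq_along(taxa) - 1L), taxa)
  n_total <- 0L
  masks <- vector("list", length(skeletons))
  parents <- vector("list", length(skeletons))
  tree_id <- vector("list", length(skeletons))
  for (ti in seq_along(skeletons)) {
    sk <- skeletons[[ti]]
    unmapped <- setdiff(sk$tip.label, names(mapping))
    if (length(unmapped) > 0L) {
      copol_stop("gene-tree leaf not covered by the mapping: ", unmapped[1])
    }
    bad <- setdiff(unique(mapping[sk$tip.label]), taxa)
    if (length(bad) > 0L) {
      copol_stop("taxon absent from the species-tree leaf set: ", bad[1])
    }
    m <- integer(sk$nn)
    m[seq_len(sk$ntip)] <- unname(taxon_bit[mapping[sk$tip.label]])
    e <- sk$edge
    for (j in seq_len(nrow(e))) {
      m[e[j, 1L]] <- bitwOr(m[e[j, 1L]], m[e[j, 2L]])
    }
    masks[[ti]] <- m
    parents[[ti]] <- ifelse(sk$parent == 0L, NA_integer_, sk$parent + n_total)
    tree_id[[ti]] <- rep(ti, sk$nn)
    n_total <- n_total + sk$nn
  }
  mask <- c(unlist(masks), -1L)           # sentinel at position n_total + 1
  parent <- unlist(parents)
  parent[is.na(parent)] <- n_total + 1L
  parent <- c(parent, n_total + 1L)
  list(
    taxa = taxa, taxon_bit = taxon_bit, n_trees = length(skeletons),
    mask = mask, parent = parent, tree_id = c(unlist(tree_id), 0L),
    full = Reduce(bitwOr, taxon_bit)
  )
}

## per-tree counts of maximal clades fully inside cluster mask C
cluster_lineages <- function(C, ctx) {
  within <- bitwAnd(ctx$mask, bitwNot(C)) == 0L
  maximal <- within & !within[ctx$parent]
  tabulate(ctx$tree_id[maximal], nbins = ctx$n_trees)
}

## total extra lineages contributed by cluster C over all trees in ctx
cluster_cost <- function(C, ctx) {
  sum(pmax(cluster_lineages(C, ctx) - 1L, 0L))
}

## extra-lineage costs of many cluster masks at once (vectorised across
## nodes x masks); returns a numeric vector parallel to `Cs`
cluster_cost_many <- function(Cs, ctx) {
  if (length(Cs) * length(ctx$mask) > 5e6) {   # chunk to bound memory
    half <- seq_len(length(Cs) %/% 2L)
    return(c(cluster_cost_many(Cs[half], ctx),
             cluster_cost_many(Cs[-half], ctx)))
  }
  within <- outer(ctx$mask, bitwNot(as.integer(Cs)), bitwAnd) == 0L
  maximal <- within & !within[ctx$parent, , drop = FALSE]
  k <- rowsum(maximal + 0L, ctx$tree_id, reorder = TRUE)
  if (rownames(k)[1L] == "0") k <- k[-1L, , drop = FALSE]   # sentinel row
  colSums(pmax(k - 1L, 0L))
}

## bitmasks of the clusters below every branch of a rooted species tree
## (all non-root nodes, pendant branches included; root cluster excluded)
species_clusters <- function(species_tree, taxon_bit) {
  st <- species_tree
  unknown <- setdiff(st$tip.label, names(taxon_bit))
  if (length(unknown) > 0L) {
    copol_stop("taxon absent from the mapping image: ", unknown[1])
  }
  nn <- ape::Ntip(st) + st$Nnode
  m <- integer(nn)
  m[seq_len(ape::Ntip(st))] <- unname(taxon_bit[st$tip.label])
  stp <- stats::reorder(st, "postorder")
  e <- stp$edge
  for (j in seq_len(nrow(e))) m[e[j, 1L]] <- bitwOr(m[e[j, 1L]], m[e[j, 2L]])
  root <- e[nrow(e), 1L]
  m[-root]
}

## ---- public scoring --------------------------------------------------------

#' Count extra lineages of a gene tree in a species tree
#'
#' Computes the deep-coalescence cost of embedding a rooted gene tree into a
#' rooted species tree under a leaf-to-taxon mapping: the sum, over species
#' branches, of (number of lineages exiting the branch - 1), where the number
#' of lineages exiting a branch with taxon cluster C is the number of maximal
#' gene-tree clades whose leaves all map into C. This equals the minimum
#' number of extra lineages over all valid coalescent embeddings.
#'
#' @param gene_tree Rooted `phylo`; leaves are allele identifiers.
#' @param species_tree Rooted `phylo`; leaves are taxon labels.
#' @param mapping Named character vector, allele -> taxon; must cover every
#'   gene-tree leaf, and every image must be a species-tree leaf.
#' @return Non-negative integer.
#' @export
count_extra_lineages <- function(gene_tree, species_tree, mapping) {
  ctx <- mdc_context(list(gene_tree), mapping, taxa = sort(species_tree$tip.label))
  cl <- species_clusters(species_tree, ctx$taxon_bit)
  sum(vapply(cl, function(C) cluster_cost(C, ctx), 0))
}

#' Total deep-coalescence score of a gene tree set
#'
#' Sums extra lineages over every tree of every locus (no per-locus
#' averaging), so loci represented by larger posterior samples carry
#' proportionally more weight.
#'
#' @param gts A `gene_tree_set`.
#' @param species_tree Rooted `phylo` over the mapped taxa.
#' @param mapping Named character vector, allele -> taxon.
#' @return An object of class `mdc_score`: list with `total` (integer) and
#'   `per_tree` (data frame: locus, tree, extra_lineages).
#' @export
total_score <- function(gts, species_tree, mapping) {
  fl <- flatten_trees(gts)
  ctx <- mdc_context(fl$trees, mapping, taxa = sort(species_tree$tip.label))
  cl <- species_clusters(species_tree, ctx$taxon_bit)
  per_tree <- integer(ctx$n_trees)
  for (C in cl) per_tree <- per_tree + pmax(cluster_lineages(C, ctx) - 1L, 0L)
  structure(
    list(total = sum(per_tree),
         per_tree = data.frame(locus = fl$locus,
                               tree = unlist(lapply(gts$trees, seq_along)),
                               extra_lineages = per_tree)),
    class = "mdc_score"
  )
}

#' @export
print.mdc_score <- function(x, ...) {
  cat("mdc_score: total =", x$total, "extra lineages over",
      nrow(x$per_tree), "gene trees\n")
  invisible(x)
}

## ---- species tree inference ------------------------------------------------

## enumerate all rooted binary shapes on taxon indices 1..n as nested pairs
all_rooted_shapes <- function(n) {
  if (n == 1L) return(list(1L))
  if (n == 2L) return(list(list(1L, 2L)))
  smaller <- all_rooted_shapes(n - 1L)
  out <- vector("list", 0L)
  for (s in smaller) {
    for (v in attach_leaf(s, n)) out[[length(out) + 1L]] <- v
  }
  out
}

## all ways to attach leaf `x` onto a shape: on every edge plus above the root
attach_leaf <- function(shape, x) {
  res <- list(list(shape, x))    # new root above the old one
  graft <- function(node) {
    ## returns all variants of `node` with x inserted somewhere strictly inside
    out <- list()
    if (is.list(node)) {
      for (side in 1:2) {
        sub <- node[[side]]
        repl <- c(list(list(sub, x)), graft(sub))
        for (r in repl) {
          nd <- node
          nd[[side]] <- r
          out[[length(out) + 1L]] <- nd
        }
      }
    }
    out
  }
  c(res, graft(shape))
}

## clusters (bitmasks, root included last) and canonical newick of a shape
shape_info <- function(shape, taxa) {
  clusters <- integer(0)
  rec <- function(node) {
    if (!is.list(node)) {
      m <- bitwShiftL(1L, node - 1L)
      clusters[[length(clusters) + 1L]] <<- m
      return(list(mask = m, nwk = taxa[node]))
    }
    a <- rec(node[[1L]]); b <- rec(node[[2L]])
    m <- bitwOr(a$mask, b$mask)
    clusters[[length(clusters) + 1L]] <<- m
    parts <- sort(c(a$nwk, b$nwk))
    list(mask = m, nwk = paste0("(", parts[1L], ",", parts[2L], ")"))
  }
  r <- rec(shape)
  list(clusters = clusters[-length(clusters)],  # drop root cluster
       newick = paste0(r$nwk, ";"))
}

#' Infer the MDC-optimal species tree
#'
#' Finds a rooted binary species tree over the mapped taxa minimizing the
#' total number of extra lineages summed over all gene trees.
#'
#' `"exhaustive"` mode enumerates every rooted binary topology (feasible for
#' at most 9 taxa). `"clusters"` mode solves the same optimum by dynamic
#' programming: for up to 12 taxa the program runs over all taxon subsets and
#' is exact; beyond that it restricts candidate clusters to those induced by
#' the gene trees, their complements, and singletons, which recovers the
#' exhaustive optimum whenever the optimal tree's clusters all appear among
#' the candidates. Ties are broken toward the lexicographically smallest
#' canonical (sorted) Newick string.
#'
#' @param gts A `gene_tree_set`.
#' @param mapping Named character vector, allele -> taxon.
#' @param mode `"clusters"` (default) or `"exhaustive"`.
#' @param skeletons Optional precomputed [tree_skeleton] list (internal
#'   optimization for repeated scoring of the same trees).
#' @return List with `tree` (rooted binary `phylo`), `score` (`mdc_score`),
#'   and `newick` (canonical string).
#' @export
infer_mdc_tree <- function(gts, mapping, mode = c("clusters", "exhaustive"),
                           skeletons = NULL) {
  mode <- mode[1L]
  if (!mode %in% c("clusters", "exhaustive")) {
    copol_stop("mode must be \"clusters\" or \"exhaustive\"")
  }
  fl <- flatten_trees(gts)
  if (length(fl$trees) < 1L) copol_stop("at least one gene tree required")
  taxa <- sort(unique(unname(mapping[intersect(names(mapping), gts$alleles)])))
  if (length(taxa) < 3L) {
    warning("fewer than 3 taxa: returning the trivial species tree")
    nwk <- if (length(taxa) == 1L) paste0("(", taxa, ");") else
      paste0("(", taxa[1L], ",", taxa[2L], ");")
    tree <- ape::read.tree(text = nwk)
    return(list(tree = tree, score = total_score(gts, tree, mapping), newick = nwk))
  }
  ctx <- mdc_context(fl$trees, mapping, taxa = taxa, skeletons = skeletons)
  memo <- new.env(parent = emptyenv())
  costf <- function(C) {
    key <- as.character(C)
    v <- memo[[key]]
    if (is.null(v)) {
      v <- cluster_cost(C, ctx)
      memo[[key]] <- v
    }
    v
  }
  best <- if (mode == "exhaustive") {
    if (length(taxa) > 9L) copol_stop("exhaustive mode supports at most 9 taxa")
    infer_exhaustive(taxa, costf)
  } else {
    infer_clusters_dp(taxa, costf, ctx)
  }
  tree <- ape::read.tree(text = best$newick)
  ## per-tree breakdown from the context already in hand
  cl <- species_clusters(tree, ctx$taxon_bit)
  per_tree <- integer(ctx$n_trees)
  for (C in cl) per_tree <- per_tree + pmax(cluster_lineages(C, ctx) - 1L, 0L)
  score <- structure(
    list(total = sum(per_tree),
         per_tree = data.frame(locus = fl$locus,
                               tree = unlist(lapply(gts$trees, seq_along)),
                               extra_lineages = per_tree)),
    class = "mdc_score")
  list(tree = tree, score = score, newick = best$newick)
}

infer_exhaustive <- function(taxa, costf) {
  shapes <- all_rooted_shapes(length(taxa))
  best_score <- Inf; best_nwk <- NULL
  for (s in shapes) {
    info <- shape_info(s, taxa)
    sc <- sum(vapply(info$clusters, costf, 0))
    if (sc < best_score || (sc == best_score && info$newick < best_nwk)) {
      best_score <- sc
      best_nwk <- info$newick
    }
  }
  list(score = best_score, newick = best_nwk)
}

## cache of per-k submask split tables: for every mask A (>= 2 taxa) the
## vectors of unordered splits (B, A\B) with the lowest taxon fixed in B
.dp_tables <- new.env(parent = emptyenv())

dp_split_table <- function(k) {
  key <- as.character(k)
  tbl <- .dp_tables[[key]]
  if (!is.null(tbl)) return(tbl)
  full <- bitwShiftL(1L, k) - 1L
  pc <- popcount(seq_len(full))
  A_order <- seq_len(full)[order(pc)]
  A_order <- A_order[pc[A_order] >= 2L]
  splits <- vector("list", full)
  for (A in A_order) {
    lowbit <- bitwAnd(A, -A)
    Bs <- integer(0)
    B <- A
    repeat {
      B <- bitwAnd(B - 1L, A)
      if (B == 0L) break
      if (bitwAnd(B, lowbit) == 0L || B == A) next   # fix lowest taxon in B
      Bs[length(Bs) + 1L] <- B
    }
    Bs <- Bs[Bs != A]
    splits[[A]] <- rbind(Bs, bitwAnd(A, bitwNot(Bs)))
  }
  tbl <- list(A_order = A_order, splits = splits)
  .dp_tables[[key]] <- tbl
  tbl
}

## exact subset dynamic program (<= 12 taxa) or candidate-restricted DP
infer_clusters_dp <- function(taxa, costf, ctx) {
  k <- length(taxa)
  full <- ctx$full
  if (k <= 12L) {
    ## every mask is visited, so precompute the full cost vector up front
    cost <- cluster_cost_many(seq_len(full), ctx)
    tbl <- dp_split_table(k)
    ## f[A] = min cost of clusters strictly inside A for a rooted tree on A;
    ## g[A] = f[A] + cost of the cluster A itself
    f <- rep(Inf, full)
    g <- rep(Inf, full)
    singles <- bitwShiftL(1L, seq_len(k) - 1L)
    f[singles] <- 0; g[singles] <- cost[singles]
    for (A in tbl$A_order) {
      sp <- tbl$splits[[A]]
      f[A] <- min(g[sp[1L, ]] + g[sp[2L, ]])
      g[A] <- f[A] + cost[A]
    }
    ## reconstruct the optimal tree, breaking ties toward the smallest
    ## canonical newick, off the scoring hot path
    nwk_memo <- character(full)
    nwk_memo[singles] <- taxa
    nwk_of <- function(A) {
      if (nzchar(nwk_memo[A])) return(nwk_memo[A])
      sp <- dp_split_table(k)$splits[[A]]
      sc <- g[sp[1L, ]] + g[sp[2L, ]]
      best <- NULL
      for (i in which(sc <= min(sc) + 1e-9)) {
        a <- nwk_of(sp[1L, i]); b <- nwk_of(sp[2L, i])
        cand <- if (a < b) paste0("(", a, ",", b, ")") else paste0("(", b, ",", a, ")")
        if (is.null(best) || cand < best) best <- cand
      }
      nwk_memo[A] <<- best
      best
    }
    return(list(score = f[full], newick = paste0(nwk_of(full), ";")))
  }
  ## large taxon sets: restrict splits to gene-tree-induced clusters,
  ## their complements, and singletons
  cand <- unique(c(ctx$mask[ctx$mask > 0L & ctx$mask != full],
                   bitwShiftL(1L, seq_len(k) - 1L)))
  cand <- unique(c(cand, bitwAnd(full, bitwNot(cand))))
  cand <- cand[cand > 0L & cand != full]
  cand <- cand[order(popcount(cand), cand)]
  f <- new.env(parent = emptyenv())
  solve <- function(A) {
    key <- as.character(A)
    got <- f[[key]]
    if (!is.null(got)) return(got)
    if (popcount(A) == 1L) {
      res <- list(score = 0, nwk = taxa[which(bitwShiftL(1L, seq_len(k) - 1L) == A)])
      f[[key]] <- res
      return(res)
    }
    best <- list(score = Inf, nwk = "")
    f[[key]] <- best                       # guard against cycles
    for (B in cand) {
      if (B >= A || bitwAnd(A, B) != B) next
      Bc <- bitwAnd(A, bitwNot(B))
      if (Bc == 0L || B > Bc) next         # unordered split
      rb <- solve(B); rc <- solve(Bc)
      sc <- rb$score + costf(B) + rc$score + costf(Bc)
      if (sc < best$score ||
          (is.finite(sc) && sc == best$score && {
            parts <- sort(c(rb$nwk, rc$nwk))
            paste0("(", parts[1L], ",", parts[2L], ")") < best$nwk
          })) {
        parts <- sort(c(rb$nwk, rc$nwk))
        best <- list(score = sc, nwk = paste0("(", parts[1L], ",", parts[2L], ")"))
        f[[key]] <- best
      }
    }
    f[[key]] <- best
    best
  }
  res <- solve(full)
  if (!is.finite(res$score)) copol_stop("cluster-restricted search found no assemblable tree")
  list(score = res$score, newick = paste0(res$nwk, ";"))
}
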