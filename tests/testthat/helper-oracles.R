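## Independent oracles used by the tests. These deliberately take the naive
## route (explicit enumeration, direct formulas) and share no code with the
## package internals they check.

## ---- brute-force deep-coalescence oracle -----------------------------------

## Minimum number of extra lineages over all coalescent embeddings of a
## rooted gene tree into a rooted species tree, by explicit enumeration of
## the species-tree node at which every gene coalescence happens.
oracle_extra_lineages <- function(gene_tree, species_tree, mapping,
                                  max_assignments = 5e5) {
  st <- species_tree
  n_sp <- ape::Ntip(st) + st$Nnode
  sp_parent <- integer(n_sp)
  sp_parent[st$edge[, 2]] <- st$edge[, 1]
  sp_root <- setdiff(st$edge[, 1], st$edge[, 2])[1]
  ## ancestor bitmask of each species node (self .. root inclusive)
  ancmask <- integer(n_sp)
  for (v in seq_len(n_sp)) {
    x <- v
    repeat {
      ancmask[v] <- bitwOr(ancmask[v], bitwShiftL(1L, x - 1L))
      if (x == sp_root) break
      x <- sp_parent[x]
    }
  }
  is_anc <- function(a, b) bitwAnd(ancmask[b], bitwShiftL(1L, a - 1L)) != 0L
  lca <- function(a, b) {
    x <- a
    while (!is_anc(x, b)) x <- sp_parent[x]
    x
  }

  gt <- gene_tree
  n_g <- ape::Ntip(gt) + gt$Nnode
  g_parent <- integer(n_g)
  g_parent[gt$edge[, 2]] <- gt$edge[, 1]
  g_root <- setdiff(gt$edge[, 1], gt$edge[, 2])[1]
  ## species image of every gene node's leaf-set LCA (postorder fill)
  loc_min <- integer(n_g)
  for (i in seq_len(ape::Ntip(gt))) {
    loc_min[i] <- which(st$tip.label == mapping[[gt$tip.label[i]]])
  }
  po <- stats::reorder(gt, "postorder")$edge
  for (j in seq_len(nrow(po))) {
    p <- po[j, 1]; ch <- po[j, 2]
    loc_min[p] <- if (loc_min[p] == 0L) loc_min[ch] else lca(loc_min[p], loc_min[ch])
  }
  internal <- (ape::Ntip(gt) + 1L):n_g
  allowed <- lapply(internal, function(v) {
    x <- loc_min[v]
    out <- x
    while (x != sp_root) {
      x <- sp_parent[x]
      out <- c(out, x)
    }
    out
  })
  if (prod(vapply(allowed, length, 1L)) > max_assignments) {
    stop("oracle instance too large to enumerate")
  }
  grid <- expand.grid(allowed, KEEP.OUT.ATTRS = FALSE)
  children <- split(gt$edge[, 2], gt$edge[, 1])
  best <- Inf
  branch_nodes <- setdiff(seq_len(n_sp), sp_root)
  for (r in seq_len(nrow(grid))) {
    loc <- loc_min
    loc[internal] <- as.integer(grid[r, ])
    ## validity: each internal node at an ancestor-or-equal of its children
    ok <- TRUE
    for (v in internal) {
      for (ch in children[[as.character(v)]]) {
        if (!is_anc(loc[v], loc[ch])) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (!ok) next
    ## lineage counts per species branch (branch above each non-root node)
    count <- integer(n_sp)
    for (v in seq_len(n_g)) {
      span <- if (v == g_root) {
        ancmask[loc[v]]                                     # up to the species root
      } else {
        bitwAnd(ancmask[loc[v]], bitwNot(ancmask[loc[g_parent[v]]]))
      }
      for (b in branch_nodes) {
        if (bitwAnd(span, bitwShiftL(1L, b - 1L)) != 0L) count[b] <- count[b] + 1L
      }
    }
    extra <- sum(pmax(count[branch_nodes] - 1L, 0L))
    if (extra < best) best <- extra
  }
  best
}

## ---- independent tree enumeration ------------------------------------------

## all rooted binary tree topologies over a label set, as Newick strings,
## by recursive bipartition (first label fixed on the left side)
all_rooted_newicks <- function(labels) {
  labels <- sort(labels)
  n <- length(labels)
  if (n == 1L) return(labels)
  out <- character(0)
  rest <- labels[-1]
  for (sz in 0:(n - 2L)) {
    picks <- if (sz == 0L) list(integer(0)) else
      utils::combn(length(rest), sz, simplify = FALSE)
    for (pick in picks) {
      left <- c(labels[1], rest[pick])
      right <- if (sz == 0L) rest else rest[-pick]
      if (length(right) == 0L) next
      for (a in all_rooted_newicks(left)) {
        for (b in all_rooted_newicks(right)) {
          out <- c(out, paste0("(", a, ",", b, ")"))
        }
      }
    }
  }
  out
}

## random rooted binary topology over given labels
random_rooted_tree <- function(labels) {
  tr <- ape::rtree(length(labels), tip.label = sample(labels))
  tr$edge.length <- NULL
  tr
}

## ---- naive formula re-implementations --------------------------------------

## mean Shannon entropy of averaged (already aligned) binary matrices,
## written as the direct double loop over rows and columns
naive_mean_entropy <- function(matrices) {
  avg <- matrices[[1]] * 0
  for (m in matrices) avg <- avg + m
  avg <- avg / length(matrices)
  total <- 0
  for (i in seq_len(nrow(avg))) {
    h <- 0
    for (j in seq_len(ncol(avg))) {
      c_ij <- avg[i, j]
      if (c_ij > 0) h <- h - c_ij * log(c_ij)
    }
    total <- total + h
  }
  unname(total / nrow(avg))
}

## non-trivial rooted clades of a tree as a sorted character set, using
## ape's prop.part as the independent clade extractor
clade_strings <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  sort(unique(vapply(pp, function(idx) paste(sort(labs[idx]), collapse = "|"), "")))
}

## expected clade set of a leaf-restricted tree: restrict every original
## clade to the kept leaves, drop empties and duplicates
restricted_clade_strings <- function(tree, keep) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  res <- vapply(pp, function(idx) {
    got <- sort(intersect(labs[idx], keep))
    if (length(got) < 2L) "" else paste(got, collapse = "|")   # trivial after restriction
  }, "")
  sort(unique(res[nzchar(res)]))
}

## all valid allele partitions of one focal taxon (exhaustive, independent
## of the package's enumeration): cartesian product of per-group capacity-2
## assignments
enumerate_valid_partitions <- function(tab, focal_taxon, k, gts = NULL) {
  fa <- tab$alleles[tab$alleles$taxon == focal_taxon, , drop = FALSE]
  if (!is.null(gts)) fa <- fa[fa$allele %in% gts$alleles, , drop = FALSE]
  groups <- split(fa$allele, paste(fa$accession, fa$locus))
  per_group <- lapply(groups, function(g) {
    grid <- expand.grid(rep(list(seq_len(k)), length(g)))
    ok <- apply(grid, 1, function(v) max(tabulate(v, nbins = k)) <= 2L)
    lapply(which(ok), function(r) stats::setNames(as.integer(grid[r, ]), g))
  })
  combos <- expand.grid(lapply(per_group, seq_along))
  lapply(seq_len(nrow(combos)), function(r) {
    assign <- unlist(lapply(seq_along(per_group), function(gi) {
      per_group[[gi]][[combos[r, gi]]]
    }))
    allele_partition(focal_taxon, k, assign)
  })
}
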