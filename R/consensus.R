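## Combination of replicate reconstructions: entropy-minimizing alignment of
## subgenome labels across runs, tree relabelling, and greedy consensus.

#' Binary membership matrix of a partition
#'
#' One row per allele, one column per subgenome; entry 1 marks the assigned
#' subgenome.
#'
#' @param p An `allele_partition`.
#' @param alleles Optional row order (default: sorted allele names).
#' @return Binary matrix with allele row names.
#' @export
membership_matrix <- function(p, alleles = NULL) {
  if (is.null(alleles)) alleles <- sort(names(p$assignment))
  missing <- setdiff(alleles, names(p$assignment))
  if (length(missing) > 0L) copol_stop("allele not in partition: ", missing[1])
  m <- matrix(0L, nrow = length(alleles), ncol = p$k,
              dimnames = list(alleles, NULL))
  m[cbind(seq_along(alleles), p$assignment[alleles])] <- 1L
  m
}

check_membership_matrices <- function(matrices) {
  if (length(matrices) == 0L) copol_stop("no membership matrices given")
  d <- dim(matrices[[1]])
  for (m in matrices) {
    if (!is.matrix(m) || !identical(dim(m), d)) {
      copol_stop("membership matrices must share identical dimensions")
    }
    rs <- rowSums(m)
    if (any(rs == 0)) copol_stop("membership matrix has an all-zero row")
  }
  invisible(d)
}

apply_alignment <- function(matrices, alignment) {
  perms <- if (inherits(alignment, "column_alignment")) alignment$perms else alignment
  if (length(perms) != length(matrices)) {
    copol_stop("alignment has ", length(perms), " permutations for ",
               length(matrices), " matrices")
  }
  Map(function(m, p) {
    out <- m
    out[, p] <- m    # column j of m becomes column p[j]
    out
  }, matrices, perms)
}

#' Mean Shannon entropy of averaged membership coefficients
#'
#' Applies the per-replicate column permutations, averages the matrices
#' element-wise, computes the Shannon entropy
#' H_i = -sum_j c_ij log(c_ij) of each allele's averaged row (natural log,
#' with 0 log 0 = 0), and returns the mean over alleles. Zero means perfect
#' agreement of the aligned replicates.
#'
#' @param matrices List of binary membership matrices of equal dimension.
#' @param alignment A `column_alignment` or list of permutations; `NULL`
#'   means identity for every replicate.
#' @return Non-negative number.
#' @export
mean_entropy <- function(matrices, alignment = NULL) {
  check_membership_matrices(matrices)
  if (is.null(alignment)) {
    alignment <- rep(list(seq_len(ncol(matrices[[1]]))), length(matrices))
  }
  aligned <- apply_alignment(matrices, alignment)
  avg <- Reduce(`+`, aligned) / length(aligned)
  h <- apply(avg, 1L, function(row) {
    nz <- row[row > 0]
    -sum(nz * log(nz))
  })
  mean(h)
}

#' Align subgenome labels across replicate reconstructions
#'
#' Finds per-replicate column permutations minimizing the mean Shannon
#' entropy of the averaged membership coefficients (label switching across
#' runs makes raw columns incomparable). The first replicate's permutation is
#' fixed to the identity, since a common permutation of all replicates leaves
#' the objective unchanged.
#'
#' `"exact"` mode enumerates all (C!)^(K-1) alignments (feasible for small C
#' and K); `"iterative"` mode (default) cycles over replicates, exactly
#' re-optimizing one permutation at a time until no improvement, with random
#' restarts. Ties are broken toward the lexicographically smallest
#' permutation tuple.
#'
#' @param matrices List of >= 2 binary membership matrices.
#' @param restarts Random restarts for iterative mode.
#' @param seed Integer seed for the restarts.
#' @param mode `"iterative"` or `"exact"`.
#' @return Object of class `column_alignment`: `perms` (list of integer
#'   permutations) and `entropy` (achieved objective).
#' @export
align_clusters <- function(matrices, restarts = 10L, seed = 1L,
                           mode = c("iterative", "exact")) {
  mode <- match.arg(mode)
  d <- check_membership_matrices(matrices)
  if (length(matrices) < 2L) copol_stop("at least 2 matrices required")
  K <- length(matrices); C <- d[2]
  perms_C <- permutations(C)
  identity_perm <- seq_len(C)
  objective <- function(perms) mean_entropy(matrices, perms)

  better <- function(cand, cand_obj, best, best_obj) {
    if (cand_obj < best_obj - 1e-12) return(TRUE)
    if (cand_obj > best_obj + 1e-12) return(FALSE)
    ## lexicographic tie-break on the flattened permutation tuple
    a <- unlist(cand); b <- unlist(best)
    i <- which(a != b)
    length(i) > 0L && a[i[1L]] < b[i[1L]]
  }

  if (mode == "exact") {
    grid <- rep(list(seq_along(perms_C)), K - 1L)
    combos <- as.matrix(expand.grid(grid))
    best <- NULL; best_obj <- Inf
    for (r in seq_len(nrow(combos))) {
      perms <- c(list(identity_perm), lapply(combos[r, ], function(i) perms_C[[i]]))
      obj <- objective(perms)
      if (is.null(best) || better(perms, obj, best, best_obj)) {
        best <- perms; best_obj <- obj
      }
    }
  } else {
    set.seed(seed)
    best <- NULL; best_obj <- Inf
    for (r in seq_len(restarts)) {
      perms <- c(list(identity_perm),
                 if (r == 1L) rep(list(identity_perm), K - 1L)
                 else lapply(seq_len(K - 1L), function(i) sample(C)))
      obj <- objective(perms)
      repeat {
        improved <- FALSE
        for (i in seq(2L, K)) {
          loc_best <- perms[[i]]; loc_obj <- obj
          for (q in perms_C) {
            cand <- perms; cand[[i]] <- q
            co <- objective(cand)
            if (co < loc_obj - 1e-12 ||
                (abs(co - loc_obj) <= 1e-12 && paste(q, collapse = "") <
                   paste(loc_best, collapse = ""))) {
              loc_best <- q; loc_obj <- co
            }
          }
          if (!identical(loc_best, perms[[i]])) {
            perms[[i]] <- loc_best
            if (loc_obj < obj - 1e-12) improved <- TRUE
            obj <- loc_obj
          }
        }
        if (!improved) break
      }
      if (is.null(best) || better(perms, obj, best, best_obj)) {
        best <- perms; best_obj <- obj
      }
    }
    ## never worse than the identity alignment
    id_obj <- objective(rep(list(identity_perm), K))
    if (id_obj < best_obj - 1e-12) {
      best <- rep(list(identity_perm), K); best_obj <- id_obj
    }
  }
  structure(list(perms = best, entropy = best_obj), class = "column_alignment")
}

#' @export
print.column_alignment <- function(x, ...) {
  cat("column_alignment:", length(x$perms), "replicates, mean entropy",
      format(x$entropy, digits = 6), "\n")
  invisible(x)
}

#' Relabel subgenome pseudo-taxa in species trees
#'
#' Leaf `"Pj"` of the i-th tree becomes `"P(perm_i(j))"`; topology untouched.
#'
#' @param trees List of `phylo` species trees with pseudo-taxon leaves
#'   `P1..PC`.
#' @param alignment A `column_alignment` (or list of permutations), one
#'   permutation per tree.
#' @return List of relabelled `phylo` trees.
#' @export
relabel_trees <- function(trees, alignment) {
  perms <- if (inherits(alignment, "column_alignment")) alignment$perms else alignment
  if (length(trees) != length(perms)) {
    copol_stop("number of trees and permutations differ")
  }
  Map(function(tr, perm) {
    expected <- paste0("P", seq_along(perm))
    missing <- setdiff(expected, tr$tip.label)
    if (length(missing) > 0L) {
      copol_stop("tree lacks pseudo-taxon leaf ", missing[1])
    }
    is_p <- tr$tip.label %in% expected
    j <- as.integer(sub("^P", "", tr$tip.label[is_p]))
    tr$tip.label[is_p] <- paste0("P", perm[j])
    tr
  }, trees, perms)
}

#' Greedy consensus of rooted species trees
#'
#' Ranks clades by their frequency across the input trees and adds them in
#' decreasing order whenever compatible (nested or disjoint) with the clades
#' already accepted; clades below `min_frequency` are excluded when
#' `min_frequency > 0`. Retained internal nodes are annotated with their
#' clade frequency via node labels.
#'
#' @param trees Non-empty list of rooted `phylo` trees sharing one leaf set.
#' @param min_frequency Minimum clade frequency to retain (0 keeps all
#'   greedily compatible clades).
#' @return A rooted `phylo`; `node.label` holds clade frequencies.
#' @export
greedy_consensus <- function(trees, min_frequency = 0) {
  if (length(trees) == 0L) copol_stop("empty tree list")
  leaf_set <- sort(trees[[1]]$tip.label)
  counts <- new.env(parent = emptyenv())
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), leaf_set)) {
      copol_stop("trees do not share one leaf set")
    }
    for (cl in rooted_clades(tr)) {
      key <- paste(cl, collapse = "\r")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]], 1L) / length(trees)
  clades <- strsplit(keys, "\r", fixed = TRUE)
  sizes <- vapply(clades, length, 1L)
  keep <- sizes > 1L & sizes < length(leaf_set)
  clades <- clades[keep]; freq <- freq[keep]; sizes <- sizes[keep]
  if (min_frequency > 0) {
    clades <- clades[freq >= min_frequency]
    sizes <- sizes[freq >= min_frequency]
    freq <- freq[freq >= min_frequency]
  }
  ## deterministic rank: frequency desc, size desc, then label string
  ord <- order(-freq, -sizes, vapply(clades, paste, "", collapse = ","))
  accepted <- list(); accepted_freq <- numeric(0)
  for (i in ord) {
    cl <- clades[[i]]
    ok <- all(vapply(accepted, function(a) {
      inter <- length(intersect(a, cl))
      inter == 0L || inter == length(a) || inter == length(cl)
    }, TRUE))
    if (ok) {
      accepted[[length(accepted) + 1L]] <- cl
      accepted_freq <- c(accepted_freq, freq[i])
    }
  }
  build_tree_from_clades(leaf_set, accepted, accepted_freq)
}

## clades (tip-label sets below each internal node, root included) of a
## rooted tree
rooted_clades <- function(tr) {
  nn <- ape::Ntip(tr) + tr$Nnode
  below <- vector("list", nn)
  below[seq_len(ape::Ntip(tr))] <- as.list(tr$tip.label)
  trp <- stats::reorder(tr, "postorder")
  e <- trp$edge
  for (j in seq_len(nrow(e))) {
    below[[e[j, 1L]]] <- c(below[[e[j, 1L]]], below[[e[j, 2L]]])
  }
  lapply(below[(ape::Ntip(tr) + 1L):nn], sort)
}

## assemble a rooted tree (Newick, node labels = frequencies) from a
## compatible clade set over leaf_set
build_tree_from_clades <- function(leaf_set, clades, freqs) {
  build <- function(members, label) {
    ## children: maximal accepted clades strictly inside `members`
    inside <- which(vapply(clades, function(cl) {
      length(cl) < length(members) && all(cl %in% members)
    }, TRUE))
    inside <- inside[order(-vapply(clades[inside], length, 1L))]
    used <- character(0)
    parts <- character(0)
    for (i in inside) {
      cl <- clades[[i]]
      if (any(cl %in% used)) next
      parts <- c(parts, build(cl, as.character(freqs[i])))
      used <- c(used, cl)
    }
    singles <- setdiff(members, used)
    parts <- sort(c(parts, singles))
    if (length(parts) == 1L) parts else
      paste0("(", paste(parts, collapse = ","), ")", label)
  }
  nwk <- paste0(build(leaf_set, "1"), ";")
  ape::read.tree(text = nwk)
}
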