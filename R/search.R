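## Tabu search over constrained allele partitions of one focal polyploid.
##
## The optimization variable is the assignment of every focal allele to one of
## k subgenomes (k <= ploidy/2), subject to the single-copy constraint: for
## each focal accession, locus and subgenome, at most two of that accession's
## alleles at that locus may share the subgenome. The objective is the total
## number of extra lineages of the MDC species tree implied by the partition.

#' Construct an allele partition
#'
#' @param focal_taxon Polyploid taxon whose alleles are partitioned.
#' @param k Number of subgenomes (at most ploidy/2).
#' @param assignment Named integer vector: focal allele -> subgenome in 1..k.
#' @return Object of class `allele_partition`.
#' @export
allele_partition <- function(focal_taxon, k, assignment) {
  if (!is_count(k)) copol_stop("k must be a positive integer")
  assignment <- stats::setNames(as.integer(assignment), names(assignment))
  if (is.null(names(assignment)) || any(!nzchar(names(assignment)))) {
    copol_stop("assignment must be a named vector (names are alleles)")
  }
  if (any(assignment < 1L) || any(assignment > k)) {
    copol_stop("subgenome indices must lie in 1..k")
  }
  structure(list(focal_taxon = focal_taxon, k = as.integer(k),
                 assignment = assignment),
            class = "allele_partition")
}

#' @export
print.allele_partition <- function(x, ...) {
  cat("allele_partition:", length(x$assignment), "alleles of", x$focal_taxon,
      "in", x$k, "subgenomes\n")
  invisible(x)
}

## focal alleles with their accession/locus, optionally restricted to a
## gene tree set's allele universe
focal_allele_table <- function(tab, focal_taxon, gts = NULL) {
  fa <- tab$alleles[tab$alleles$taxon == focal_taxon, , drop = FALSE]
  if (nrow(fa) == 0L) copol_stop("no alleles for focal taxon ", focal_taxon)
  if (any(fa$ploidy < 4L)) copol_stop("focal taxon ", focal_taxon, " is not polyploid")
  if (!is.null(gts)) fa <- fa[fa$allele %in% gts$alleles, , drop = FALSE]
  if (nrow(fa) == 0L) copol_stop("no focal alleles present in the gene trees")
  fa
}

#' Validate a partition against the capacity constraint
#'
#' Checks that every focal allele is assigned and that no accession places
#' more than two alleles of one locus into the same subgenome.
#'
#' @param p An `allele_partition`.
#' @param tab An `accession_table`.
#' @param gts Optional `gene_tree_set` restricting the allele universe.
#' @return `TRUE` invisibly, or an error.
#' @export
validate_partition <- function(p, tab, gts = NULL) {
  fa <- focal_allele_table(tab, p$focal_taxon, gts)
  missing <- setdiff(fa$allele, names(p$assignment))
  if (length(missing) > 0L) copol_stop("unassigned focal allele: ", missing[1])
  sub <- p$assignment[fa$allele]
  counts <- table(paste(fa$accession, fa$locus, sub, sep = "\r"))
  if (any(counts > 2L)) {
    copol_stop("more than two alleles of one accession-locus in a subgenome")
  }
  invisible(TRUE)
}

## enumerate all capacity-respecting assignment vectors for m alleles into k
## subgenomes (used for uniform sampling and for brute-force oracles)
valid_assignments <- function(m, k) {
  if (m > 2L * k) copol_stop(m, " alleles exceed the 2k = ", 2L * k, " subgenome slots")
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), m)))
  ok <- apply(grid, 1L, function(v) all(tabulate(v, nbins = k) <= 2L))
  grid[ok, , drop = FALSE]
}

#' Draw a uniformly random valid partition
#'
#' For each focal accession-locus group, one assignment is drawn uniformly at
#' random among all capacity-respecting assignments of that group's alleles,
#' independently across groups.
#'
#' @param tab An `accession_table`.
#' @param focal_taxon Focal polyploid taxon.
#' @param k Number of subgenomes; defaults to ploidy/2.
#' @param seed Optional integer seed (`set.seed` is called when non-NULL).
#' @param gts Optional `gene_tree_set` restricting the allele universe.
#' @return An `allele_partition`, valid by construction.
#' @export
random_partition <- function(tab, focal_taxon, k = NULL, seed = NULL, gts = NULL) {
  fa <- focal_allele_table(tab, focal_taxon, gts)
  n <- fa$ploidy[1L]
  if (is.null(k)) k <- n %/% 2L
  if (k > n %/% 2L) copol_stop("k must not exceed ploidy/2 = ", n %/% 2L)
  if (!is.null(seed)) set.seed(seed)
  groups <- split(fa$allele, paste(fa$accession, fa$locus, sep = "\r"))
  assignment <- integer(0)
  for (g in groups[order(names(groups))]) {
    va <- valid_assignments(length(g), k)
    pick <- va[sample.int(nrow(va), 1L), ]
    assignment[g] <- pick
  }
  allele_partition(focal_taxon, k, assignment)
}

#' Enumerate the move neighborhood of a partition
#'
#' SHIFT moves reassign one allele to a different subgenome that has free
#' capacity at that allele's accession-locus; SWAP moves exchange the
#' subgenome indices of two alleles of the same accession and locus that sit
#' in different subgenomes. Every returned move preserves validity.
#'
#' @param p An `allele_partition`.
#' @param tab An `accession_table`.
#' @param gts Optional `gene_tree_set` restricting the allele universe.
#' @return List of moves; each move is a list with `type` (`"shift"` or
#'   `"swap"`), `alleles`, `from`, `to`.
#' @export
neighborhood <- function(p, tab, gts = NULL) {
  fa <- focal_allele_table(tab, p$focal_taxon, gts)
  moves <- list()
  groups <- split(fa$allele, paste(fa$accession, fa$locus, sep = "\r"))
  for (g in groups[order(names(groups))]) {
    sub <- p$assignment[g]
    counts <- tabulate(sub, nbins = p$k)
    for (a in g) {
      for (s2 in seq_len(p$k)) {
        if (s2 != p$assignment[[a]] && counts[s2] < 2L) {
          moves[[length(moves) + 1L]] <-
            list(type = "shift", alleles = a, from = p$assignment[[a]], to = s2)
        }
      }
    }
    if (length(g) >= 2L) {
      pairs <- utils::combn(g, 2L, simplify = FALSE)
      for (pr in pairs) {
        s <- p$assignment[pr]
        if (s[1L] != s[2L]) {
          moves[[length(moves) + 1L]] <-
            list(type = "swap", alleles = pr, from = s, to = rev(s))
        }
      }
    }
  }
  moves
}

#' Apply a move to a partition
#' @param p An `allele_partition`.
#' @param move A move as returned by [neighborhood()].
#' @return The modified `allele_partition`.
#' @export
apply_move <- function(p, move) {
  p$assignment[move$alleles] <- move$to
  p
}

## canonical key of a partition: subgenomes relabelled by order of first
## appearance over sorted allele names (quotient over label symmetry);
## returns the key and the relabelling permutation (old -> canonical)
canonical_partition <- function(p) {
  alleles <- sort(names(p$assignment))
  sub <- p$assignment[alleles]
  relab <- integer(p$k)
  nxt <- 1L
  for (s in sub) {
    if (relab[s] == 0L) { relab[s] <- nxt; nxt <- nxt + 1L }
  }
  for (s in seq_len(p$k)) if (relab[s] == 0L) { relab[s] <- nxt; nxt <- nxt + 1L }
  list(key = paste(relab[sub], collapse = ""), relabel = relab)
}

#' Build the leaf-to-taxon mapping implied by a partition
#'
#' Diploid alleles map to their taxon; focal polyploid alleles map to
#' pseudo-taxa `"P1"..."Pk"` according to the partition.
#'
#' @param tab An `accession_table`.
#' @param partition An `allele_partition`.
#' @return Named character vector, allele -> taxon label.
#' @export
partition_mapping <- function(tab, partition) {
  ttab <- tab$alleles
  dip <- ttab[ttab$ploidy == 2L, , drop = FALSE]
  mapping <- stats::setNames(dip$taxon, dip$allele)
  mapping[names(partition$assignment)] <- paste0("P", partition$assignment)
  mapping
}

#' Score a partition via MDC species-tree inference
#'
#' Maps diploid alleles to their taxa and focal alleles to subgenome
#' pseudo-taxa, then infers the MDC-optimal species tree; the partition's
#' score is that tree's total number of extra lineages. Deterministic given
#' the partition. Results are cached per canonical partition (subgenome
#' labels are a symmetry of the objective).
#'
#' @param p An `allele_partition`.
#' @param gts A `gene_tree_set`, already pruned of non-focal polyploids.
#' @param tab An `accession_table`.
#' @param mode Inference mode passed to [infer_mdc_tree()].
#' @param cache Optional environment used as score cache across calls.
#' @param skeletons Optional precomputed tree skeletons (internal
#'   optimization for repeated scoring).
#' @return List with `tree` (`phylo`), `score` (`mdc_score`).
#' @export
score_partition <- function(p, gts, tab, mode = "clusters", cache = NULL,
                            skeletons = NULL) {
  canon <- canonical_partition(p)
  if (!is.null(cache)) {
    hit <- cache[[canon$key]]
    if (!is.null(hit)) {
      ## cached tree carries canonical subgenome labels; translate back
      tree <- hit$tree
      inv <- order(canon$relabel)   # canonical -> original label
      tree$tip.label <- vapply(tree$tip.label, function(l) {
        if (grepl("^P[0-9]+$", l)) {
          paste0("P", inv[as.integer(sub("^P", "", l))])
        } else l
      }, "")
      return(list(tree = tree, score = hit$score))
    }
  }
  mapping <- partition_mapping(tab, p)
  res <- infer_mdc_tree(gts, mapping, mode = mode, skeletons = skeletons)
  if (!is.null(cache)) {
    ## store with canonical labels
    ctree <- res$tree
    ctree$tip.label <- vapply(ctree$tip.label, function(l) {
      if (grepl("^P[0-9]+$", l)) {
        paste0("P", canon$relabel[as.integer(sub("^P", "", l))])
      } else l
    }, "")
    cache[[canon$key]] <- list(tree = ctree, score = res$score)
  }
  list(tree = res$tree, score = res$score)
}

#' Tabu-search parameters
#'
#' @param tabu_tenure Iterations a reversed move attribute stays forbidden.
#' @param max_iterations Iterations per restart.
#' @param neighborhood_sample_size Candidate moves evaluated per iteration.
#' @param restarts Number of independent restarts.
#' @param rng_seed Integer seed; recorded in the result.
#' @return Object of class `tabu_params`.
#' @export
tabu_params <- function(tabu_tenure = 5L, max_iterations = 60L,
                        neighborhood_sample_size = 25L, restarts = 1L,
                        rng_seed = 1L) {
  for (v in list(tabu_tenure, max_iterations, neighborhood_sample_size, restarts)) {
    if (!is_count(v)) copol_stop("all tabu parameters must be positive integers")
  }
  structure(list(tabu_tenure = as.integer(tabu_tenure),
                 max_iterations = as.integer(max_iterations),
                 neighborhood_sample_size = as.integer(neighborhood_sample_size),
                 restarts = as.integer(restarts),
                 rng_seed = as.integer(rng_seed)),
            class = "tabu_params")
}

## tabu attributes blocked by reversing `move`: re-placing an allele into the
## subgenome it just left
move_tabu_attributes <- function(move) {
  paste(move$alleles, move$from, sep = "\r")
}

#' Tabu search for the most parsimonious allele partition
#'
#' Starting from a uniformly random valid partition, each iteration samples up
#' to `neighborhood_sample_size` moves from the shift/swap neighborhood,
#' evaluates their MDC scores, and applies the best admissible one (non-tabu,
#' or tabu but improving on the best score found so far — the aspiration
#' criterion). The reversal of the applied move is forbidden for
#' `tabu_tenure` iterations. The best partition and species tree seen across
#' all restarts are returned. Fully reproducible given `rng_seed`.
#'
#' @param gts A `gene_tree_set`, pruned of non-focal polyploids.
#' @param tab An `accession_table`.
#' @param focal_taxon Focal polyploid taxon.
#' @param params A [tabu_params()] object.
#' @param k Number of subgenomes; defaults to ploidy/2.
#' @param mode Inference mode for [infer_mdc_tree()].
#' @return Object of class `search_result`: `best_partition`, `best_tree`,
#'   `best_score` (`mdc_score`), `trace` (data frame: restart, iteration,
#'   incumbent, best), `params`.
#' @export
tabu_search <- function(gts, tab, focal_taxon, params = tabu_params(),
                        k = NULL, mode = "clusters") {
  set.seed(params$rng_seed)
  cache <- new.env(parent = emptyenv())
  skeletons <- skeletons_of(flatten_trees(gts)$trees)
  best <- NULL
  trace <- list()
  for (r in seq_len(params$restarts)) {
    p <- random_partition(tab, focal_taxon, k = k, gts = gts)
    cur <- score_partition(p, gts, tab, mode = mode, cache = cache,
                           skeletons = skeletons)
    cur_score <- cur$score$total
    if (is.null(best) || cur_score < best$score$total) {
      best <- list(partition = p, tree = cur$tree, score = cur$score)
    }
    tabu <- new.env(parent = emptyenv())    # attribute -> expiry iteration
    for (it in seq_len(params$max_iterations)) {
      moves <- neighborhood(p, tab, gts)
      if (length(moves) == 0L) break
      idx <- if (length(moves) > params$neighborhood_sample_size) {
        sort(sample.int(length(moves), params$neighborhood_sample_size))
      } else seq_along(moves)
      chosen <- NULL
      for (i in idx) {
        mv <- moves[[i]]
        cand_p <- apply_move(p, mv)
        cand <- score_partition(cand_p, gts, tab, mode = mode, cache = cache,
                                skeletons = skeletons)
        is_tabu <- any(vapply(move_tabu_attributes(list(alleles = mv$alleles, from = mv$to)),
                              function(a) {
                                exp <- tabu[[a]]
                                !is.null(exp) && exp >= it
                              }, TRUE))
        admissible <- !is_tabu || cand$score$total < best$score$total
        if (admissible &&
            (is.null(chosen) || cand$score$total < chosen$score$total)) {
          chosen <- list(move = mv, partition = cand_p, tree = cand$tree,
                         score = cand$score)
        }
      }
      if (is.null(chosen)) {
        trace[[length(trace) + 1L]] <-
          data.frame(restart = r, iteration = it, incumbent = cur_score,
                     best = best$score$total)
        next
      }
      p <- chosen$partition
      cur_score <- chosen$score$total
      for (a in move_tabu_attributes(chosen$move)) {
        tabu[[a]] <- it + params$tabu_tenure
      }
      if (cur_score < best$score$total) {
        best <- list(partition = p, tree = chosen$tree, score = chosen$score)
      }
      trace[[length(trace) + 1L]] <-
        data.frame(restart = r, iteration = it, incumbent = cur_score,
                   best = best$score$total)
    }
  }
  structure(
    list(best_partition = best$partition, best_tree = best$tree,
         best_score = best$score,
         trace = do.call(rbind, trace) %||%
           data.frame(restart = integer(0), iteration = integer(0),
                      incumbent = integer(0), best = integer(0)),
         params = params),
    class = "search_result"
  )
}

#' @export
print.search_result <- function(x, ...) {
  cat("search_result: best score", x$best_score$total, "extra lineages;",
      nrow(x$trace), "iterations logged\n")
  invisible(x)
}
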