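## Gene tree and accession-table I/O, validation, and pruning.

#' Construct a validated gene tree set
#'
#' A gene tree set groups rooted, allele-labelled gene trees by locus. Within
#' one locus all trees must share the same leaf-label set (e.g. a posterior
#' sample for that marker); across loci the labels may differ. Leaf labels are
#' allele identifiers and must be unique within each tree.
#'
#' @param trees_by_locus Named list; each element is a list of rooted
#'   `ape::phylo` trees (a bare `phylo` or `multiPhylo` is also accepted) for
#'   one locus. Names are the locus identifiers.
#' @return An object of class `gene_tree_set` with elements `loci` (character),
#'   `trees` (list of lists of `phylo`), and `alleles` (sorted character vector
#'   of all leaf labels).
#' @export
gene_tree_set <- function(trees_by_locus) {
  if (length(trees_by_locus) == 0L) copol_stop("gene tree set must contain at least one locus")
  if (is.null(names(trees_by_locus)) || any(names(trees_by_locus) == "")) {
    copol_stop("trees_by_locus must be a named list (names are locus ids)")
  }
  trees <- lapply(trees_by_locus, function(x) {
    if (inherits(x, "phylo")) x <- list(x)
    if (inherits(x, "multiPhylo")) x <- unclass(x)
    x
  })
  for (locus in names(trees)) {
    tl <- trees[[locus]]
    if (length(tl) == 0L) copol_stop("locus ", locus, " has no trees")
    ref <- NULL
    for (i in seq_along(tl)) {
      tr <- tl[[i]]
      if (!inherits(tr, "phylo")) copol_stop("locus ", locus, ": element ", i, " is not a phylo tree")
      if (anyDuplicated(tr$tip.label)) {
        copol_stop("locus ", locus, ", tree ", i, ": duplicated leaf label")
      }
      if (!ape::is.rooted(tr)) {
        copol_stop("locus ", locus, ", tree ", i,
                   ": tree is unrooted (basal polytomy); rooted gene trees are required")
      }
      labs <- sort(tr$tip.label)
      if (is.null(ref)) ref <- labs
      else if (!identical(ref, labs)) {
        copol_stop("locus ", locus, ": trees have differing leaf sets (tree ", i, ")")
      }
    }
  }
  structure(
    list(
      loci = names(trees),
      trees = trees,
      alleles = sort(unique(unlist(lapply(trees, function(tl) tl[[1]]$tip.label))))
    ),
    class = "gene_tree_set"
  )
}

#' @export
print.gene_tree_set <- function(x, ...) {
  nt <- sum(vapply(x$trees, length, 1L))
  cat("gene_tree_set:", length(x$loci), "loci,", nt, "trees,",
      length(x$alleles), "alleles\n")
  invisible(x)
}

#' Number of trees in a gene tree set
#' @param gts A `gene_tree_set`.
#' @return Integer.
#' @export
n_trees <- function(gts) sum(vapply(gts$trees, length, 1L))

## flatten to a plain list of trees with a parallel locus vector
flatten_trees <- function(gts) {
  list(
    trees = unlist(gts$trees, recursive = FALSE, use.names = FALSE),
    locus = rep(gts$loci, vapply(gts$trees, length, 1L))
  )
}

#' Read gene trees from a Newick file
#'
#' The file holds one rooted Newick tree per line. `loci_spec` assigns line
#' ranges to loci; with `NULL` all trees form a single locus `"L1"`.
#'
#' @param path Path to a Newick file, one tree per line.
#' @param loci_spec `NULL`, or a data frame with columns `locus`, `from`, `to`
#'   (1-based inclusive line ranges, non-overlapping, covering lines present in
#'   the file).
#' @return A [gene_tree_set()].
#' @export
parse_gene_trees <- function(path, loci_spec = NULL) {
  if (!file.exists(path)) copol_stop("gene tree file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) copol_stop("no trees in ", path)
  trees <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    tr <- tryCatch(ape::read.tree(text = lines[ln]),
                   error = function(e) NULL, warning = function(w) NULL)
    if (is.null(tr) || !inherits(tr, "phylo")) {
      copol_stop("malformed Newick at line ", ln, " of ", path)
    }
    trees[[i]] <- tr
  }
  if (is.null(loci_spec)) {
    loci_spec <- data.frame(locus = "L1", from = 1L, to = length(keep))
  }
  required <- c("locus", "from", "to")
  if (!is.data.frame(loci_spec) || !all(required %in% names(loci_spec))) {
    copol_stop("loci_spec must be a data frame with columns locus, from, to")
  }
  by_locus <- list()
  assigned <- integer(0)
  for (r in seq_len(nrow(loci_spec))) {
    idx <- seq.int(loci_spec$from[r], loci_spec$to[r])
    if (any(idx < 1L) || any(idx > length(trees))) {
      copol_stop("loci_spec range for locus ", loci_spec$locus[r],
                 " is outside 1..", length(trees))
    }
    if (any(idx %in% assigned)) copol_stop("loci_spec ranges overlap")
    assigned <- c(assigned, idx)
    lc <- as.character(loci_spec$locus[r])
    by_locus[[lc]] <- c(by_locus[[lc]], trees[idx])
  }
  gene_tree_set(by_locus)
}

#' Write gene trees to a Newick file
#'
#' One tree per line, loci in order; returns the `loci_spec` describing the
#' layout so that `parse_gene_trees(path, spec)` round-trips.
#'
#' @param gts A `gene_tree_set`.
#' @param path Output path.
#' @return Invisibly, the loci_spec data frame.
#' @export
write_gene_trees <- function(gts, path) {
  lines <- character(0)
  spec <- data.frame(locus = character(0), from = integer(0), to = integer(0))
  at <- 1L
  for (locus in gts$loci) {
    tl <- gts$trees[[locus]]
    lines <- c(lines, vapply(tl, function(t) ape::write.tree(t), ""))
    spec <- rbind(spec, data.frame(locus = locus, from = at, to = at + length(tl) - 1L))
    at <- at + length(tl)
  }
  writeLines(lines, path)
  invisible(spec)
}

#' Construct a validated accession table
#'
#' The accession table maps each sampled allele to an accession (individual),
#' each accession to a taxon and a ploidy level. Ploidy 2 marks diploids;
#' ploidy >= 4 marks polyploids. An accession of ploidy n may list at most n
#' alleles per locus, and every allele identifier belongs to exactly one
#' accession.
#'
#' @param records Data frame with columns `accession`, `taxon`, `ploidy`,
#'   `locus`, `alleles` (comma-separated allele identifiers), one row per
#'   accession-locus pair.
#' @return An object of class `accession_table` with elements `records` (the
#'   input, normalised), `alleles` (long data frame: allele, accession, taxon,
#'   ploidy, locus) and `accessions` (accession, taxon, ploidy).
#' @export
accession_table <- function(records) {
  required <- c("accession", "taxon", "ploidy", "locus", "alleles")
  if (!is.data.frame(records) || !all(required %in% names(records))) {
    copol_stop("records must have columns ", paste(required, collapse = ", "))
  }
  records <- records[required]
  records$accession <- as.character(records$accession)
  records$taxon <- as.character(records$taxon)
  records$locus <- as.character(records$locus)
  records$ploidy <- as.integer(records$ploidy)
  records$alleles <- as.character(records$alleles)
  if (any(is.na(records$ploidy)) || any(records$ploidy < 2L) || any(records$ploidy %% 2L != 0L)) {
    copol_stop("ploidy must be a positive even integer (>= 2)")
  }
  acc <- unique(records[c("accession", "taxon", "ploidy")])
  if (anyDuplicated(acc$accession)) {
    copol_stop("accession listed with inconsistent taxon or ploidy")
  }
  long <- do.call(rbind, lapply(seq_len(nrow(records)), function(r) {
    al <- trimws(strsplit(records$alleles[r], ",")[[1]])
    al <- al[nzchar(al)]
    if (length(al) > records$ploidy[r]) {
      copol_stop("accession ", records$accession[r], ", locus ", records$locus[r],
                 ": ", length(al), " alleles exceed ploidy ", records$ploidy[r])
    }
    if (length(al) == 0L) return(NULL)
    data.frame(allele = al, accession = records$accession[r],
               taxon = records$taxon[r], ploidy = records$ploidy[r],
               locus = records$locus[r], stringsAsFactors = FALSE)
  }))
  if (is.null(long) || nrow(long) == 0L) copol_stop("accession table contains no alleles")
  if (anyDuplicated(long$allele)) {
    dup <- long$allele[duplicated(long$allele)][1]
    copol_stop("allele identifier assigned more than once: ", dup)
  }
  structure(list(records = records, alleles = long, accessions = acc),
            class = "accession_table")
}

#' @export
print.accession_table <- function(x, ...) {
  cat("accession_table:", nrow(x$accessions), "accessions,",
      length(unique(x$alleles$taxon)), "taxa,", nrow(x$alleles), "alleles\n")
  invisible(x)
}

#' Read an accession table from a TSV file
#'
#' Tab-separated, one row per accession-locus pair:
#' `accession <TAB> taxon <TAB> ploidy <TAB> locus <TAB> allele1,allele2,...`.
#' Lines starting with `#` are ignored.
#'
#' @param path Path to the TSV file.
#' @return An [accession_table()].
#' @export
parse_accession_table <- function(path) {
  if (!file.exists(path)) copol_stop("accession table not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          col.names = c("accession", "taxon", "ploidy", "locus", "alleles"))
  accession_table(df)
}

#' Write an accession table to TSV
#' @param tab An `accession_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_accession_table <- function(tab, path) {
  utils::write.table(tab$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Prune alleles of non-focal polyploids from gene trees
#'
#' Subgenome memberships are reconstructed for one polyploid taxon at a time;
#' alleles belonging to any other polyploid (ploidy >= 4, taxon different from
#' `focal_taxon`) are removed from every gene tree. Degree-2 internal nodes
#' created by the removal are suppressed and the root is retained.
#'
#' @param gts A `gene_tree_set`.
#' @param tab An `accession_table`.
#' @param focal_taxon Name of the polyploid taxon under study.
#' @return A pruned `gene_tree_set` (identical to the input when no other
#'   polyploid is present).
#' @export
prune_nonfocal_polyploids <- function(gts, tab, focal_taxon) {
  ttab <- tab$alleles
  if (!focal_taxon %in% ttab$taxon[ttab$ploidy >= 4L]) {
    copol_stop("focal_taxon ", focal_taxon, " is not a polyploid taxon in the table")
  }
  drop <- ttab$allele[ttab$ploidy >= 4L & ttab$taxon != focal_taxon]
  drop <- intersect(drop, gts$alleles)
  if (length(drop) == 0L) return(gts)
  pruned <- lapply(gts$trees, function(tl) {
    lapply(tl, function(tr) {
      here <- intersect(drop, tr$tip.label)
      if (length(here) == 0L) return(tr)
      if (length(tr$tip.label) - length(here) < 2L) {
        copol_stop("pruning would leave a gene tree with fewer than 2 leaves")
      }
      ape::drop.tip(tr, here, collapse.singles = TRUE)
    })
  })
  gene_tree_set(pruned)
}

#' Write allele partitions as a CLUMPP-compatible indfile
#'
#' Each partition becomes one block of binary membership coefficients: one row
#' per allele, one column per subgenome, blocks separated by a blank line. All
#' partitions must cover the same allele set with the same number of
#' subgenomes. Row order (sorted allele identifiers) is identical across
#' blocks and is recorded in a sidecar file `<path>.alleles`.
#'
#' @param partitions List of [allele_partition()] objects.
#' @param path Output path.
#' @return Invisibly, the character vector of alleles in row order.
#' @export
write_indfile <- function(partitions, path) {
  if (length(partitions) == 0L) copol_stop("no partitions to write")
  alleles <- sort(names(partitions[[1]]$assignment))
  k <- partitions[[1]]$k
  for (p in partitions) {
    if (!identical(sort(names(p$assignment)), alleles) || p$k != k) {
      copol_stop("partitions have inconsistent allele sets or subgenome counts")
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(partitions)) {
    m <- membership_matrix(partitions[[i]], alleles = alleles)
    utils::write.table(m, con, sep = " ", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    if (i < length(partitions)) writeLines("", con)
  }
  writeLines(alleles, paste0(path, ".alleles"))
  invisible(alleles)
}

#' Read an indfile written by [write_indfile()]
#'
#' @param path Path to the indfile; the sidecar `<path>.alleles` must exist.
#' @return List of binary matrices (rows named by allele).
#' @export
read_indfile <- function(path) {
  if (!file.exists(path)) copol_stop("indfile not found: ", path)
  sidecar <- paste0(path, ".alleles")
  if (!file.exists(sidecar)) copol_stop("allele-order sidecar not found: ", sidecar)
  alleles <- readLines(sidecar)
  lines <- readLines(path)
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  blocks <- lapply(blocks, function(b) b[nzchar(trimws(b))])
  blocks <- blocks[vapply(blocks, length, 1L) > 0L]
  lapply(blocks, function(b) {
    m <- do.call(rbind, lapply(strsplit(trimws(b), "[[:space:]]+"), as.numeric))
    if (nrow(m) != length(alleles)) {
      copol_stop("indfile block has ", nrow(m), " rows; expected ", length(alleles))
    }
    rownames(m) <- alleles
    m
  })
}
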