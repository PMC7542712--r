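test_that("gene tree parsing validates rooting, loci and leaf sets", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a1,a2),(b1,b2));", f)
  gts <- parse_gene_trees(f)
  expect_s3_class(gts, "gene_tree_set")
  expect_equal(length(gts$loci), 1L)
  expect_equal(n_trees(gts), 1L)
  expect_setequal(gts$alleles, c("a1", "a2", "b1", "b2"))

  ## same locus, differing leaf sets -> validation error naming the locus
  writeLines(c("((a1,a2),(b1,b2));", "((a1,a2),(b1,c1));"), f)
  expect_error(parse_gene_trees(f), "L1")

  ## unrooted (basal trifurcation) is rejected, not silently rooted
  writeLines("(a1,a2,b1);", f)
  expect_error(parse_gene_trees(f), "unrooted")

  ## malformed newick reports the line number
  writeLines(c("((a1,a2),(b1,b2));", "((a1,a2),(b1,b2)"), f)
  expect_error(parse_gene_trees(f), "line 2")
})

test_that("loci_spec assigns line ranges to loci and round-trips", {
  loci <- paste0("L", 1:10)
  trees <- lapply(loci, function(lc) {
    lab <- paste0(c("a", "b", "c", "d"), "_", lc)
    lapply(1:100, function(i) {
      tr <- ape::rtree(4, tip.label = sample(lab))
      tr$edge.length <- NULL
      tr
    })
  })
  names(trees) <- loci
  gts <- gene_tree_set(trees)
  expect_equal(n_trees(gts), 1000L)

  f <- withr::local_tempfile(fileext = ".nwk")
  spec <- write_gene_trees(gts, f)
  back <- parse_gene_trees(f, spec)
  expect_identical(back$loci, gts$loci)
  expect_identical(back$alleles, gts$alleles)
  for (lc in loci) {
    expect_equal(
      vapply(back$trees[[lc]], ape::write.tree, ""),
      vapply(gts$trees[[lc]], ape::write.tree, "")
    )
  }
})

test_that("accession table parses, validates and round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("acc1\tTaxA\t2\tL1\ta1,a2",
               "acc9\tPolyX\t4\tL1\tx1,x2,x3,x4"), f)
  tab <- parse_accession_table(f)
  expect_s3_class(tab, "accession_table")
  expect_equal(nrow(tab$accessions), 2L)
  expect_equal(sum(tab$alleles$taxon == "PolyX"), 4L)
  expect_equal(unique(tab$alleles$ploidy[tab$alleles$taxon == "PolyX"]), 4L)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_accession_table(tab, f2)
  back <- parse_accession_table(f2)
  expect_identical(back$records, tab$records)
  expect_identical(back$alleles, tab$alleles)

  ## odd ploidy
  writeLines("acc1\tTaxA\t3\tL1\ta1,a2", f)
  expect_error(parse_accession_table(f), "even")
  ## more alleles than ploidy
  writeLines("acc1\tTaxA\t4\tL1\ta1,a2,a3,a4,a5", f)
  expect_error(parse_accession_table(f), "exceed")
  ## duplicate allele across accessions
  writeLines(c("acc1\tTaxA\t2\tL1\ta1,a2",
               "acc2\tTaxB\t2\tL1\ta1,b2"), f)
  expect_error(parse_accession_table(f), "more than once")
})

test_that("pruning removes only non-focal polyploid alleles", {
  tab <- accession_table(rbind(
    data.frame(accession = "acc1", taxon = "A", ploidy = 2L, locus = "L1",
               alleles = "a1"),
    data.frame(accession = "acc2", taxon = "X", ploidy = 4L, locus = "L1",
               alleles = "x1,x2"),
    data.frame(accession = "acc3", taxon = "Y", ploidy = 4L, locus = "L1",
               alleles = "y1")
  ))
  gts <- gene_tree_set(list(L1 = tree("((x1,y1),(a1,x2));")))

  pruned <- prune_nonfocal_polyploids(gts, tab, "X")
  expect_setequal(pruned$trees$L1[[1]]$tip.label, c("x1", "x2", "a1"))

  ## identity when no other polyploid exists
  tab2 <- accession_table(tab$records[tab$records$taxon != "Y", ])
  gts2 <- gene_tree_set(list(L1 = tree("(x1,(a1,x2));")))
  expect_identical(prune_nonfocal_polyploids(gts2, tab2, "X"), gts2)

  ## idempotent
  expect_identical(prune_nonfocal_polyploids(pruned, tab, "X"), pruned)

  ## non-polyploid focal taxon is rejected
  expect_error(prune_nonfocal_polyploids(gts, tab, "A"), "polyploid")
})

test_that("pruned topology equals the leaf restriction of the original", {
  ## 16-leaf tree holding 4 alleles of a second tetraploid Y
  set.seed(202)
  a_labels <- c(paste0("x", 1:4), paste0("y", 1:4),
                paste0("a", 1:4), paste0("b", 1:4))
  rows <- rbind(
    data.frame(accession = "aX", taxon = "X", ploidy = 4L, locus = "L1",
               alleles = paste(paste0("x", 1:4), collapse = ",")),
    data.frame(accession = "aY", taxon = "Y", ploidy = 4L, locus = "L1",
               alleles = paste(paste0("y", 1:4), collapse = ",")),
    data.frame(accession = "aA", taxon = "A", ploidy = 2L, locus = "L1",
               alleles = "a1,a2"),
    data.frame(accession = "aA2", taxon = "A", ploidy = 2L, locus = "L1",
               alleles = "a3,a4"),
    data.frame(accession = "aB", taxon = "B", ploidy = 2L, locus = "L1",
               alleles = "b1,b2"),
    data.frame(accession = "aB2", taxon = "B", ploidy = 2L, locus = "L1",
               alleles = "b3,b4")
  )
  tab <- accession_table(rows)
  for (rep_i in 1:5) {
    tr <- random_rooted_tree(a_labels)
    gts <- gene_tree_set(list(L1 = tr))
    pruned <- prune_nonfocal_polyploids(gts, tab, "X")
    keep <- setdiff(a_labels, paste0("y", 1:4))
    ptr <- pruned$trees$L1[[1]]
    expect_equal(length(ptr$tip.label), 12L)
    ## clade sets must match the independent restriction of the original
    expect_identical(clade_strings(ptr), restricted_clade_strings(tr, keep))
  }
})

test_that("pruning commutes with leaf restriction", {
  tab <- accession_table(rbind(
    data.frame(accession = "aX", taxon = "X", ploidy = 4L, locus = "L1",
               alleles = "x1,x2"),
    data.frame(accession = "aY", taxon = "Y", ploidy = 4L, locus = "L1",
               alleles = "y1,y2"),
    data.frame(accession = "aA", taxon = "A", ploidy = 2L, locus = "L1",
               alleles = "a1,a2"),
    data.frame(accession = "aB", taxon = "B", ploidy = 2L, locus = "L1",
               alleles = "b1,b2")
  ))
  set.seed(77)
  labels <- c("x1", "x2", "y1", "y2", "a1", "a2", "b1", "b2")
  for (i in 1:5) {
    tr <- random_rooted_tree(labels)
    restrict <- c("x1", "x2", "y1", "a1", "b1", "b2")
    ## prune then restrict
    p1 <- prune_nonfocal_polyploids(gene_tree_set(list(L1 = tr)), tab, "X")
    r1 <- ape::keep.tip(p1$trees$L1[[1]], setdiff(restrict, c("y1", "y2")))
    ## restrict then prune
    r2t <- ape::keep.tip(tr, restrict)
    p2 <- prune_nonfocal_polyploids(gene_tree_set(list(L1 = r2t)), tab, "X")
    expect_identical(clade_strings(r1), clade_strings(p2$trees$L1[[1]]))
  }
})

test_that("indfile blocks are one-hot, ordered, and parse back", {
  p1 <- allele_partition("X", 2L, c(x1 = 1L, x2 = 1L, x3 = 2L, x4 = 2L))
  p2 <- allele_partition("X", 2L, c(x1 = 1L, x2 = 2L, x3 = 1L, x4 = 2L))
  f <- withr::local_tempfile(fileext = ".ind")

  write_indfile(list(p1, p2), f)
  blocks <- read_indfile(f)
  expect_length(blocks, 2L)
  for (b in blocks) {
    expect_equal(dim(b), c(4L, 2L))
    expect_equal(unname(rowSums(b)), rep(1, 4))
    expect_true(all(b %in% c(0, 1)))
  }
  expect_identical(rownames(blocks[[1]]), sort(names(p1$assignment)))
  expect_equal(blocks[[1]], unname_dim(membership_matrix(p1)))
  expect_equal(blocks[[2]], unname_dim(membership_matrix(p2)))

  ## single partition -> single block
  write_indfile(list(p1), f)
  expect_length(read_indfile(f), 1L)

  ## many replicate blocks
  many <- rep(list(p1, p2), 48)
  write_indfile(many, f)
  expect_length(read_indfile(f), 96L)

  ## inconsistent allele sets rejected
  p3 <- allele_partition("X", 2L, c(z1 = 1L, z2 = 2L))
  expect_error(write_indfile(list(p1, p3), f), "inconsistent")
})
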