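test_that("random partitions are valid by construction", {
  tab <- toy_table()
  gts <- toy_gts()
  for (s in 1:20) {
    p <- random_partition(tab, "X", seed = s, gts = gts)
    expect_silent(validate_partition(p, tab, gts))
    ## saturated tetraploid locus: each subgenome gets exactly 2 alleles
    for (lc in c("L1", "L2")) {
      sub <- p$assignment[paste0("x", 1:4, "_", lc)]
      expect_equal(sort(unname(tabulate(sub, nbins = 2))), c(2L, 2L))
    }
  }
  ## a diploid cannot be a focal taxon
  expect_error(random_partition(tab, "A", seed = 1), "not polyploid")
  ## k above ploidy/2 rejected
  expect_error(random_partition(tab, "X", k = 3, seed = 1), "ploidy/2")
})

test_that("random partitions are uniform over valid assignments", {
  ## tetraploid with only 2 alleles at one locus, k = 2: the 4 valid
  ## assignments (1,1),(1,2),(2,1),(2,2) must be equally likely
  tab <- accession_table(rbind(
    data.frame(accession = "accA", taxon = "A", ploidy = 2L, locus = "L1",
               alleles = "a1"),
    data.frame(accession = "accX", taxon = "X", ploidy = 4L, locus = "L1",
               alleles = "x1,x2")
  ))
  n <- 8000
  set.seed(424)
  seen <- vapply(seq_len(n), function(i) {
    p <- random_partition(tab, "X", k = 2L)
    paste(p$assignment[c("x1", "x2")], collapse = "")
  }, "")
  counts <- table(factor(seen, levels = c("11", "12", "21", "22")))
  expect_equal(length(counts), 4L)
  ## each configuration within 3 sigma of n/4
  sigma <- sqrt(n * 0.25 * 0.75)
  expect_true(all(abs(counts - n / 4) < 3 * sigma))
})

test_that("neighborhood enumerates exactly the capacity-respecting moves", {
  tab <- accession_table(rbind(
    data.frame(accession = "accA", taxon = "A", ploidy = 2L, locus = "L1",
               alleles = "a1"),
    data.frame(accession = "accX", taxon = "X", ploidy = 4L, locus = "L1",
               alleles = "x1,x2,x3,x4"),
    data.frame(accession = "accX", taxon = "X", ploidy = 4L, locus = "L2",
               alleles = "x5")
  ))
  ## L1 saturated with counts (2,2): 0 shifts, 4 swaps; L2 counts (1,0):
  ## 1 shift, 0 swaps
  p <- allele_partition("X", 2L, c(x1 = 1L, x2 = 1L, x3 = 2L, x4 = 2L, x5 = 1L))
  mv <- neighborhood(p, tab)
  types <- vapply(mv, function(m) m$type, "")
  expect_equal(sum(types == "swap"), 4L)
  expect_equal(sum(types == "shift"), 1L)
  shifts <- mv[types == "shift"]
  expect_equal(shifts[[1]]$alleles, "x5")
  expect_equal(shifts[[1]]$to, 2L)

  ## every move keeps the partition valid (checked exhaustively)
  for (m in mv) {
    expect_silent(validate_partition(apply_move(p, m), tab))
  }
})

test_that("every reachable partition in a full search stays valid", {
  tab <- toy_table(loci = "L1")
  gts <- toy_gts(loci = "L1")
  p <- random_partition(tab, "X", seed = 3, gts = gts)
  seen <- character(0)
  frontier <- list(p)
  while (length(frontier) > 0 && length(seen) < 50) {
    q <- frontier[[1]]; frontier <- frontier[-1]
    key <- paste(q$assignment[sort(names(q$assignment))], collapse = "")
    if (key %in% seen) next
    seen <- c(seen, key)
    for (m in neighborhood(q, tab, gts)) {
      q2 <- apply_move(q, m)
      expect_silent(validate_partition(q2, tab, gts))
      frontier[[length(frontier) + 1L]] <- q2
    }
  }
  expect_gt(length(seen), 1)
})

test_that("partition scores are symmetric under subgenome relabeling", {
  tab <- toy_table()
  gts <- toy_gts()
  p <- toy_true_partition()
  swapped <- allele_partition("X", 2L, 3L - p$assignment)
  s1 <- score_partition(p, gts, tab)
  s2 <- score_partition(swapped, gts, tab)
  expect_equal(s1$score$total, s2$score$total)
})

test_that("the true partition scores no worse than any mixing partition", {
  ## full enumeration on the allotetraploid toy: the partition keeping the
  ## A-like and B-like alleles apart must attain the minimum score
  tab <- toy_table()
  gts <- toy_gts()
  all_p <- enumerate_valid_partitions(tab, "X", 2L, gts)
  scores <- vapply(all_p, function(p) score_partition(p, gts, tab)$score$total, 0)
  truth <- toy_true_partition()
  s_true <- score_partition(truth, gts, tab)$score$total
  expect_equal(s_true, min(scores))
})

test_that("score caching returns identical results", {
  tab <- toy_table()
  gts <- toy_gts()
  cache <- new.env()
  p <- toy_true_partition()
  r1 <- score_partition(p, gts, tab, cache = cache)
  r2 <- score_partition(p, gts, tab, cache = cache)          # cache hit
  swapped <- allele_partition("X", 2L, 3L - p$assignment)
  r3 <- score_partition(swapped, gts, tab, cache = cache)    # symmetric hit
  expect_equal(r2$score$total, r1$score$total)
  expect_equal(r3$score$total, r1$score$total)
  expect_identical(ape::write.tree(r2$tree), ape::write.tree(r1$tree))
  ## the symmetric hit must return r1's tree with P1 and P2 exchanged
  t3 <- r3$tree
  t3$tip.label <- chartr("12", "21", t3$tip.label)  # only P labels contain digits
  expect_identical(clade_strings(t3), clade_strings(r1$tree))
})

test_that("tabu search attains the brute-force optimum on a toy instance", {
  tab <- toy_table()
  gts <- toy_gts()
  all_p <- enumerate_valid_partitions(tab, "X", 2L, gts)
  opt <- min(vapply(all_p, function(p) score_partition(p, gts, tab)$score$total, 0))
  res <- tabu_search(gts, tab, "X",
                     params = tabu_params(tabu_tenure = 3L, max_iterations = 25L,
                                          neighborhood_sample_size = 100L,
                                          rng_seed = 7L))
  expect_equal(res$best_score$total, opt)
  ## the best-so-far trace is non-increasing and ends at the best score
  expect_true(all(diff(res$trace$best) <= 0))
  expect_equal(utils::tail(res$trace$best, 1), res$best_score$total)
  ## never worse than the start
  expect_lte(res$best_score$total, res$trace$incumbent[1])
})

test_that("tabu search is reproducible given the seed", {
  tab <- toy_table()
  gts <- toy_gts()
  params <- tabu_params(max_iterations = 8L, neighborhood_sample_size = 6L,
                        rng_seed = 99L)
  r1 <- tabu_search(gts, tab, "X", params = params)
  r2 <- tabu_search(gts, tab, "X", params = params)
  expect_identical(r1$best_partition$assignment, r2$best_partition$assignment)
  expect_identical(r1$trace, r2$trace)
  expect_identical(ape::write.tree(r1$best_tree), ape::write.tree(r2$best_tree))
})

test_that("k = 1 reduces to treating the polyploid as a single taxon", {
  tab <- toy_table(loci = "L1")
  ## diploid-like focal accession: 2 alleles per locus
  rows <- tab$records
  rows$alleles[rows$taxon == "X"] <- "x1_L1,x2_L1"
  tab2 <- accession_table(rows)
  gt <- tree("(((a1_L1,a2_L1),(x1_L1,x2_L1)),((b1_L1,b2_L1),(c1_L1,c2_L1)));")
  gts <- gene_tree_set(list(L1 = gt))
  p1 <- allele_partition("X", 1L, c(x1_L1 = 1L, x2_L1 = 1L))
  s <- score_partition(p1, gts, tab2)
  mapping <- stats::setNames(
    c("A", "A", "B", "B", "C", "C", "XX", "XX"),
    c("a1_L1", "a2_L1", "b1_L1", "b2_L1", "c1_L1", "c2_L1", "x1_L1", "x2_L1"))
  direct <- infer_mdc_tree(gts, mapping)
  expect_equal(s$score$total, direct$score$total)
})
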