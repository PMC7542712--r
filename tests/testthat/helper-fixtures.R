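## Small fixture builders shared across test files. All fixtures are built in
## code; nothing is read from disk except round-trip temporaries.

tree <- function(nwk) ape::read.tree(text = nwk)

## three diploids (A, B, C; one accession, alleles a1/a2 etc. per locus) plus
## one tetraploid accession (taxon X, alleles x1..x4 per locus) over `loci`
toy_table <- function(loci = c("L1", "L2")) {
  rows <- do.call(rbind, lapply(loci, function(lc) {
    rbind(
      data.frame(accession = "accA", taxon = "A", ploidy = 2L, locus = lc,
                 alleles = paste0("a1_", lc, ",a2_", lc)),
      data.frame(accession = "accB", taxon = "B", ploidy = 2L, locus = lc,
                 alleles = paste0("b1_", lc, ",b2_", lc)),
      data.frame(accession = "accC", taxon = "C", ploidy = 2L, locus = lc,
                 alleles = paste0("c1_", lc, ",c2_", lc)),
      data.frame(accession = "accX", taxon = "X", ploidy = 4L, locus = lc,
                 alleles = paste0("x1_", lc, ",x2_", lc, ",x3_", lc, ",x4_", lc))
    )
  }))
  accession_table(rows)
}

## gene trees for toy_table in which x1/x2 behave like taxon A alleles and
## x3/x4 like taxon B alleles (a clean allotetraploid signal)
toy_gts <- function(loci = c("L1", "L2")) {
  trees <- lapply(loci, function(lc) {
    s <- function(x) paste0(x, "_", lc)
    tree(sprintf(
      "((((%s,%s),(%s,%s)),((%s,%s),(%s,%s))),(%s,%s));",
      s("a1"), s("a2"), s("x1"), s("x2"),
      s("b1"), s("b2"), s("x3"), s("x4"),
      s("c1"), s("c2")))
  })
  names(trees) <- loci
  gene_tree_set(trees)
}

## the partition of toy_gts that separates the A-like from the B-like alleles
toy_true_partition <- function(loci = c("L1", "L2")) {
  assign <- integer(0)
  for (lc in loci) {
    assign[paste0(c("x1", "x2"), "_", lc)] <- 1L
    assign[paste0(c("x3", "x4"), "_", lc)] <- 2L
  }
  allele_partition("X", 2L, assign)
}

## random one-hot membership matrix (n alleles x C subgenomes)
random_onehot <- function(n, C) {
  m <- matrix(0L, n, C, dimnames = list(paste0("al", seq_len(n)), NULL))
  m[cbind(seq_len(n), sample.int(C, n, replace = TRUE))] <- 1L
  m
}

## permute the columns of a membership matrix (column j -> perm[j])
permute_cols <- function(m, perm) {
  out <- m
  out[, perm] <- m
  out
}

## numeric matrix with row names only (normalises storage mode for comparison)
unname_dim <- function(m) {
  out <- matrix(as.numeric(m), nrow(m))
  rownames(out) <- rownames(m)
  out
}
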