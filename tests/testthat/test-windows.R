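ann_chrom <- function(positions, chromosome = "chr1", prefix = "s") {
  data.frame(snp_id = sprintf("%s%s_%02d", prefix, chromosome,
                              seq_along(positions)),
             chromosome = chromosome, position = as.integer(positions),
             region_class = "intergenic", gene_id = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("gene windows group genic SNPs per gene in genomic order", {
  ann <- data.frame(
    snp_id = c("a", "b", "c", "d"), chromosome = "chr1",
    position = c(10L, 20L, 30L, 40L),
    region_class = c("exonic", "intronic", "exonic", "intergenic"),
    gene_id = c("g1", "g1", "g2", NA), stringsAsFactors = FALSE)
  gw <- build_gene_windows(ann)
  expect_equal(nrow(gw), 2)
  expect_equal(gw$members[[which(gw$gene_id == "g1")]], c("a", "b"))
  expect_equal(gw$members[[which(gw$gene_id == "g2")]], "c")
  expect_equal(gw$locus_id[gw$gene_id == "g1"], "gene_chr1_10")
  multi <- gw[gw$n_snps >= 2, ]
  expect_equal(multi$gene_id, "g1")
  expect_equal(nrow(build_gene_windows(ann_chrom(c(10, 20)))), 0)
})

test_that("slide3 windows form disjoint triples with per-chromosome leftovers", {
  s1 <- build_slide3_windows(ann_chrom(seq(100, 700, 100)))  # 7 SNPs
  expect_equal(nrow(s1), 2)
  expect_length(attr(s1, "unassigned"), 1)

  s2 <- build_slide3_windows(ann_chrom(c(100, 200)))
  expect_equal(nrow(s2), 0)
  expect_length(attr(s2, "unassigned"), 2)

  ann <- rbind(ann_chrom(c(100, 200, 300), "chr1"),
               ann_chrom(c(100, 200, 300, 400), "chr2"))
  s3 <- build_slide3_windows(ann)
  expect_equal(nrow(s3), 2)          # windows never span chromosomes
  expect_length(attr(s3, "unassigned"), 1)
  expect_equal(s3$chromosome, c("chr1", "chr2"))
})

test_that("kb10 windows chain adjacent gaps and exclude unlinked SNPs", {
  k1 <- build_kb10_windows(ann_chrom(c(100, 5000, 9000, 25000, 30000)))
  expect_equal(nrow(k1$loci), 2)
  expect_equal(k1$loci$n_snps, c(3L, 2L))
  expect_equal(k1$loci$start, c(100L, 25000L))
  expect_length(k1$excluded, 0)

  k2 <- build_kb10_windows(ann_chrom(c(100, 20000, 40000)))
  expect_equal(nrow(k2$loci), 0)
  expect_length(k2$excluded, 3)
})

test_that("kb10 and slide3 structural invariants hold on random fixtures", {
  for (seed in 1:50) {
    ann <- rand_annotation(seed)
    if (!nrow(ann)) next
    s <- build_slide3_windows(ann)
    n_by_chrom <- table(ann$chromosome)
    expect_equal(nrow(s), sum(n_by_chrom %/% 3))
    expect_length(attr(s, "unassigned"), sum(n_by_chrom %% 3))
    used <- unlist(s$members)
    expect_false(anyDuplicated(used) > 0)  # every SNP in at most one locus

    k <- build_kb10_windows(ann)
    members <- unlist(k$loci$members)
    # excluded + members partition the input
    expect_setequal(c(members, k$excluded), ann$snp_id)
    expect_false(anyDuplicated(c(members, k$excluded)) > 0)
    expect_true(all(k$loci$n_snps >= 2))
    pos <- stats::setNames(ann$position, ann$snp_id)
    for (i in seq_len(nrow(k$loci))) {
      gaps <- diff(pos[k$loci$members[[i]]])
      expect_true(all(gaps <= 10000) && all(gaps > 0))
    }
    # consecutive loci on one chromosome are separated by more than 10 kb
    for (ch in unique(k$loci$chromosome)) {
      l <- k$loci[k$loci$chromosome == ch, ]
      if (nrow(l) > 1) expect_true(all(l$start[-1] - l$end[-nrow(l)] > 10000))
    }
  }
})

test_that("haplotype calling concatenates homozygous calls", {
  calls <- rbind(c(0L, 2L, 0L),
                 c(2L, 2L, 2L),
                 c(0L, NA, 0L),
                 c(0L, 1L, 0L))
  g <- tiny_geno(calls)
  loci <- make_loci("slide3", "chr1", c("m01", "m02", "m03"),
                    c(100L, 200L, 300L))
  hc <- call_haplotypes(loci, g)
  expect_equal(unname(hc$alleles[, 1]), c("ABA", "BBB", NA, NA))
  expect_equal(hc$tables[[1]], c(ABA = 1L, BBB = 1L))
})

test_that("a missing or heterozygous member call makes the locus missing", {
  g <- tiny_geno(rbind(c(0L, NA), c(1L, 0L), c(2L, 2L)))
  loci <- make_loci("kb10", "chr1", c("m01", "m02"), c(100L, 200L))
  hc <- call_haplotypes(loci, g)
  expect_equal(unname(hc$alleles[, 1]), c(NA, NA, "BB"))
})

test_that("haplotype allele tables count distinct strings per sample", {
  calls <- rbind(matrix(rep(c(0L, 0L), 10), ncol = 2, byrow = TRUE),
                 matrix(rep(c(2L, 2L), 10), ncol = 2, byrow = TRUE))
  g <- tiny_geno(calls)
  hc <- call_haplotypes(make_loci("kb10", "chr1", c("m01", "m02"),
                                  c(100L, 200L)), g)
  expect_equal(hc$tables[[1]], c(AA = 10L, BB = 10L))
  expect_equal(length(hc$tables[[1]]), 2)
})

test_that("calling a locus with an absent member SNP errors", {
  g <- tiny_geno(rbind(c(0L, 2L)))
  loci <- make_loci("gene", "chr1", c("m01", "zzz"), c(100L, 200L))
  expect_error(call_haplotypes(loci, g), "absent.*zzz")
})

test_that("distinct alleles are bounded by 2^k and invariant to sample order", {
  set.seed(42)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    n <- sample(5:40, 1)
    calls <- matrix(sample(c(0L, 2L), n * k, replace = TRUE), nrow = n)
    g <- tiny_geno(calls)
    loci <- make_loci("slide3", "chr1", sprintf("m%02d", 1:k),
                      seq_len(k) * 100L)
    hc <- call_haplotypes(loci, g)
    expect_lte(length(hc$tables[[1]]), min(2^k, n))
    perm <- sample(n)
    g2 <- tiny_geno(calls[perm, , drop = FALSE],
                    sample_ids = sprintf("s%02d", perm))
    hc2 <- call_haplotypes(loci, g2)
    expect_equal(hc2$tables[[1]], hc$tables[[1]])
  }
})
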