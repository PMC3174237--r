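test_that("MAF filter is strictly greater-than and drops monomorphic SNPs", {
  # m01: maf 0.05 exactly (one het in 10 samples = 1/20 alleles);
  # m02: monomorphic; m03: maf 0.2
  calls <- cbind(c(1L, rep(0L, 9)), rep(0L, 10),
                 c(2L, 2L, rep(0L, 8)))
  colnames(calls) <- NULL
  g <- tiny_geno(calls)
  expect_equal(unname(maf(g)), c(0.05, 0, 0.2))
  expect_setequal(maf_filter(g, 0.05), "m03")  # 0.05 exactly is excluded
  expect_setequal(maf_filter(g, 0.01), c("m01", "m03"))
  expect_length(intersect(maf_filter(g), "m02"), 0)
})

test_that("MAF filter matches a brute-force recount on simulated data", {
  g <- simulate_genotypes(small_sim(31))
  kept <- maf_filter(g, 0.05)
  brute <- character(0)
  for (id in g$snps$snp_id) {
    cc <- g$calls[, id]
    cc <- cc[!is.na(cc)]
    nB <- sum(cc)                       # dosage coding: sum = B count
    f <- min(nB, 2 * length(cc) - nB) / (2 * length(cc))
    if (f > 0.05) brute <- c(brute, id)
  }
  expect_setequal(kept, brute)
})

test_that("R^2 landmarks from two-locus haplotype counts", {
  expect_equal(ld_pairs(geno_from_hap_counts(50, 0, 0, 50))$r2, 1)
  expect_equal(ld_pairs(geno_from_hap_counts(25, 25, 25, 25))$r2, 0)
  p <- ld_pairs(geno_from_hap_counts(40, 10, 10, 40))
  expect_equal(p$r2, 0.36, tolerance = 1e-12)
  expect_equal(p$n_informative, 100L)
  expect_equal(p$distance_bp, 1000L)
})

test_that("R^2 equals the squared Pearson correlation of 0/1 codes", {
  set.seed(5)
  for (rep in 1:25) {
    cnt <- stats::rmultinom(1, sample(20:120, 1), stats::rgamma(4, 1))
    g <- geno_from_hap_counts(cnt[1], cnt[2], cnt[3], cnt[4])
    p <- ld_pairs(g, min_informative = 5)
    x <- g$calls[, 1] / 2
    y <- g$calls[, 2] / 2
    if (nrow(p)) {
      expect_equal(p$r2, unname(stats::cor(x, y)^2), tolerance = 1e-12)
    } else {
      # skipped only when a SNP is monomorphic or the pair is too sparse
      expect_true(stats::sd(x) == 0 || stats::sd(y) == 0 || length(x) < 5)
    }
  }
})

test_that("R^2 is invariant to allele relabeling and sample order", {
  g <- geno_from_hap_counts(40, 15, 5, 40)
  base <- ld_pairs(g)
  flip <- g$calls
  flip[, 1] <- 2L - flip[, 1]  # swap A and B at the first SNP
  g2 <- tiny_geno(flip, positions = g$snps$position)
  expect_equal(ld_pairs(g2)$r2, base$r2)
  expect_equal(ld_pairs(g2)$p_value, base$p_value)
  set.seed(2)
  perm <- sample(nrow(g$calls))
  g3 <- tiny_geno(g$calls[perm, ], positions = g$snps$position,
                  sample_ids = rownames(g$calls)[perm])
  expect_equal(ld_pairs(g3)$r2, base$r2)
})

test_that("heterozygous and missing calls are excluded from haplotype counts", {
  g <- geno_from_hap_counts(30, 0, 0, 30)
  calls <- g$calls
  calls[1, 1] <- 1L    # het at one SNP
  calls[2, 2] <- NA    # missing at the other
  g2 <- tiny_geno(calls, positions = g$snps$position)
  expect_equal(ld_pairs(g2)$n_informative, 58L)
  expect_equal(ld_pairs(g2)$r2, 1)
})

test_that("pairs below the informative-sample cutoff are skipped with a report", {
  g <- geno_from_hap_counts(3, 2, 2, 3)
  p <- ld_pairs(g, min_informative = 20)
  expect_equal(nrow(p), 0)
  expect_equal(attr(p, "n_skipped_few"), 1L)
  expect_message(expect_null(pairwise_r2(g, "m01", "m02",
                                         min_informative = 20)),
                 "skipped")
})

test_that("exact test matches landmarks and handles degenerate margins", {
  expect_equal(exact_test_p(matrix(c(10, 0, 0, 10), 2, byrow = TRUE)),
               2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(exact_test_p(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(exact_test_p(matrix(c(0, 0, 7, 9), 2, byrow = TRUE)), 1)
  expect_equal(exact_test_p(matrix(c(0, 0, 0, 0), 2)), 1)
})

test_that("exact test equals full enumeration for every table with total <= 14", {
  for (tot in 1:14) {
    parts <- t(utils::combn(tot + 3, 3))
    for (r in seq_len(nrow(parts))) {
      cuts <- parts[r, ]
      tab <- c(cuts[1] - 1, cuts[2] - cuts[1] - 1, cuts[3] - cuts[2] - 1,
               tot + 3 - cuts[3])
      expect_equal(fisher_p_vec(tab[1], tab[2], tab[3], tab[4]),
                   fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                   tolerance = 1e-12)
    }
  }
})

test_that("exact test agrees with fisher.test and the oracle on random tables (total <= 30)", {
  set.seed(11)
  for (rep in 1:200) {
    tab <- as.vector(stats::rmultinom(1, sample(1:30, 1), rep(0.25, 4)))
    p <- fisher_p_vec(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p, fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
    m <- matrix(tab, 2, byrow = TRUE)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-9)
    }
  }
})

test_that("LD summary uses both denominators for the R^2 > cut column", {
  pairs <- data.frame(
    snp_i = letters[1:10], snp_j = LETTERS[1:10], chromosome = "chr1",
    distance_bp = 1:10 * 100L,
    r2 = c(0.5, 0.3, 0.05, 0.02, rep(0.01, 6)),
    p_value = c(0.001, 0.005, 0.002, 0.009, rep(0.5, 6)),
    n_informative = 50L, stringsAsFactors = FALSE)
  s <- summarize_ld(pairs, alpha = 0.01, r2_cut = 0.1)
  all_row <- s[s$chromosome == "All", ]
  expect_equal(all_row$pct_sig, 40)
  expect_equal(all_row$pct_sig_r2_all, 20)
  expect_equal(all_row$pct_sig_r2_of_sig, 50)
  # single chromosome: overall equals the per-chromosome row
  expect_equal(unname(unlist(s[1, -1])), unname(unlist(all_row[-1])))

  pairs$p_value <- 0.5
  s2 <- summarize_ld(pairs)
  expect_equal(s2$pct_sig, c(0, 0))
  expect_equal(s2$pct_sig_r2_of_sig, c(0, 0))
  expect_true(all(s2$no_sig_flag))
})

test_that("decay distance interpolates between bin centers on the R^2 = 0.1 crossing", {
  mk <- function(d, r2) data.frame(snp_i = "a", snp_j = "b",
                                   chromosome = "chr1", distance_bp = d,
                                   r2 = r2, p_value = 0.5,
                                   n_informative = 50L)
  pairs <- rbind(mk(800, 0.4), mk(4000, 0.2), mk(15000, 0.05))
  dc <- decay_curve(pairs, bin_edges = c(0, 2000, 8000, 30000))
  # bin means 0.4, 0.2, 0.05 at centers 1, 5, 19 kb; crossing after 5 kb
  expect_equal(dc$decay_distance_bp,
               5000 + (19000 - 5000) * (0.2 - 0.1) / (0.2 - 0.05))
  expect_equal(dc$censored, "none")
  expect_equal(decay_distance(dc), dc$decay_distance_bp)

  low <- decay_curve(mk(800, 0.05), bin_edges = c(0, 2000, 8000))
  expect_equal(low$censored, "low")
  expect_equal(decay_distance(low), 0)

  high <- decay_curve(rbind(mk(800, 0.4), mk(4000, 0.3)),
                      bin_edges = c(0, 2000, 8000))
  expect_equal(high$censored, "high")
  expect_equal(decay_distance(high), Inf)

  expect_error(decay_curve(mk(800, 0.4), bin_edges = c(5, 2, 100)),
               "increasing")
})

test_that("square per-chromosome matrices mirror the pair table", {
  g <- simulate_genotypes(small_sim(33))
  pairs <- ld_pairs(g, snp_ids = maf_filter(g))
  m <- ld_matrices(pairs, "chr1")
  expect_true(isSymmetric(m$r2))
  expect_true(isSymmetric(m$p))
  row <- pairs[pairs$chromosome == "chr1", ][7, ]
  expect_equal(m$r2[row$snp_i, row$snp_j], row$r2)
  expect_equal(m$p[row$snp_j, row$snp_i], row$p_value)
})
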