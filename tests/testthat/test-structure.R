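test_that("Rogers distance landmarks: identity, opposite homozygotes, hom vs het", {
  g <- tiny_geno(rbind(c(0L, 2L, 0L), c(0L, 2L, 0L), c(2L, 0L, 2L)))
  expect_equal(rogers_distance(g, "s01", "s02"), 0)
  expect_equal(rogers_distance(g, "s01", "s03"), 1)
  g2 <- tiny_geno(rbind(0L, 1L))
  expect_equal(rogers_distance(g2, "s01", "s02"), 0.5)
})

test_that("the distance matrix matches pairwise scalar computation with missing data", {
  g <- simulate_genotypes(small_sim(81))
  D <- rogers_distance_matrix(g)
  expect_equal(diag(D), stats::setNames(rep(0, n_samples(g)),
                                        g$samples$sample_id))
  expect_equal(D, t(D))
  ids <- sample(g$samples$sample_id, 6)
  for (i in 1:5) {
    expect_equal(D[ids[i], ids[i + 1]],
                 rogers_distance(g, ids[i], ids[i + 1]))
  }
  expect_true(all(D >= 0 & D <= 1))
})

test_that("a pair sharing no non-missing locus is an error", {
  g <- tiny_geno(rbind(c(0L, NA), c(NA, 2L)))
  expect_error(rogers_distance(g, "s01", "s02"), "undefined pair")
  expect_error(rogers_distance_matrix(g), "undefined pair")
})

test_that("Rogers distance is a metric on complete data", {
  g <- simulate_genotypes(small_sim(82, missing_rate = 0))
  D <- rogers_distance_matrix(g)
  set.seed(1)
  n <- n_samples(g)
  for (rep in 1:100) {
    ijk <- sample(n, 3)
    expect_lte(D[ijk[1], ijk[3]],
               D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-12)
  }
  # identity of indiscernibles at the call level
  calls <- g$calls
  calls[2, ] <- calls[1, ]
  g2 <- tiny_geno(calls, positions = g$snps$position,
                  chromosome = g$snps$chromosome)
  expect_equal(rogers_distance(g2, "s01", "s02"), 0)
})

test_that("three taxa join as a star with the classic limb lengths", {
  d <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  expect_equal(write_newick(tr), "(A:0.000000,B:2.000000,C:4.000000);")
})

test_that("an additive 4-taxon matrix is recovered exactly", {
  # unrooted tree ((A,B),(C,D)) with limbs 1,2,3,4 and internal branch 5
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 1 + 2
  d["A", "C"] <- d["C", "A"] <- 1 + 5 + 3
  d["A", "D"] <- d["D", "A"] <- 1 + 5 + 4
  d["B", "C"] <- d["C", "B"] <- 2 + 5 + 3
  d["B", "D"] <- d["D", "B"] <- 2 + 5 + 4
  d["C", "D"] <- d["D", "C"] <- 3 + 4
  tr <- neighbor_joining(d)
  expect_equal(phylo_splits(tr, ref = rownames(d)), nj_ls_oracle(d)$splits)
  expect_equal(nj_ls_oracle(d)$sse, 0, tolerance = 1e-18)
  # recovered branch lengths: tip limbs in tip order after matching labels
  cd <- as.matrix(ape::cophenetic.phylo(tr))[rownames(d), rownames(d)]
  expect_equal(cd, d, tolerance = 1e-9)
})

test_that("NJ recovers random additive trees and matches the exhaustive LS oracle (4-7 taxa)", {
  for (n in 4:7) {
    for (rep in 1:2) {
      ra <- random_additive(n, seed = n * 10 + rep)
      tr <- neighbor_joining(ra$d)
      # additive matrix: NJ must reproduce the generating topology ...
      expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ra$tree)), 0,
                   ignore_attr = TRUE)
      # ... which is also the unique zero-residual least-squares topology
      orc <- nj_ls_oracle(ra$d)
      expect_equal(phylo_splits(tr, ref = rownames(ra$d)), orc$splits)
      expect_lt(orc$sse, 1e-12)
      cd <- as.matrix(ape::cophenetic.phylo(tr))[rownames(ra$d),
                                                 rownames(ra$d)]
      expect_equal(cd, ra$d, tolerance = 1e-8)
    }
  }
})

test_that("NJ agrees with an independent NJ implementation on noisy matrices", {
  for (seed in 1:5) {
    ra <- random_additive(8, seed = 100 + seed)
    set.seed(seed)
    noise <- matrix(stats::runif(64, 0, 0.01), 8, 8)
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    d <- ra$d + noise
    expect_equal(ape::dist.topo(ape::unroot(neighbor_joining(d)),
                                ape::unroot(ape::nj(d))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("invalid distance matrices are rejected", {
  d <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(neighbor_joining(d), "symmetric")
  d3 <- matrix(c(0, -1, 1, -1, 0, 1, 1, 1, 0), 3, 3)
  expect_error(neighbor_joining(d3), "non-negative")
  expect_error(neighbor_joining(matrix(0, 2, 2)), "at least 3")
})

test_that("Newick export quotes awkward labels and round-trips", {
  d <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
              dimnames = list(c("line 1", "B", "C"), c("line 1", "B", "C")))
  tr <- neighbor_joining(d)
  nwk <- write_newick(tr)
  expect_match(nwk, "'line 1'", fixed = TRUE)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- ape::read.tree(path)
  back$tip.label <- unquote_label(back$tip.label)  # ape keeps the quotes
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(ape::dist.topo(back, tr), 0, ignore_attr = TRUE)

  ra <- random_additive(9, seed = 77)
  tr2 <- neighbor_joining(ra$d)
  write_newick(tr2, path)
  back2 <- ape::read.tree(path)
  expect_equal(ape::dist.topo(ape::unroot(back2), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
  # branch lengths survive the 6-decimal serialization
  cb <- as.matrix(ape::cophenetic.phylo(back2))
  ct <- as.matrix(ape::cophenetic.phylo(tr2))
  expect_equal(cb[rownames(ct), colnames(ct)], ct, tolerance = 1e-4)
})

test_that("the deepest split of a two-subpopulation panel separates the sets", {
  hits <- 0
  for (seed in 1:3) {
    g <- simulate_genotypes(small_sim(seed + 90))
    sp <- deepest_split(neighbor_joining(rogers_distance_matrix(g)))
    labs <- set_labels(g)
    pure <- length(unique(labs[sp$left])) == 1 &&
      length(unique(labs[sp$right])) == 1
    hits <- hits + pure
  }
  expect_gte(hits, 2)
})
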