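# Independent oracles used to cross-check the package's statistics, plus
# small fixture builders. Oracles are deliberately written as brute force:
# explicit double loops, full enumerations, exhaustive searches.

# PIC by the literal double loop over allele pairs.
pic_oracle <- function(p) {
  s <- 1 - sum(p^2)
  n <- length(p)
  if (n >= 2) {
    for (j in seq_len(n - 1)) {
      for (k in (j + 1):n) s <- s - 2 * p[j]^2 * p[k]^2
    }
  }
  s
}

# Two-sided Fisher p for [[a, b], [c, d]] by full hypergeometric enumeration
# with choose() only.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  xs <- max(0, k - n):min(k, m)
  pr <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  pobs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# Region classification by a brute scan over every (gene, exon) interval,
# replicating the earliest-span / lexicographic tie rule.
classify_oracle <- function(chromosome, position, models) {
  best <- NULL
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i, ]
    if (g$chromosome == chromosome && g$start <= position &&
        g$end >= position) {
      if (is.null(best) || g$start < best$start ||
          (g$start == best$start && g$gene_id < best$gene_id)) best <- g
    }
  }
  if (is.null(best))
    return(list(region_class = "intergenic", gene_id = NA_character_))
  in_exon <- FALSE
  ex <- models$exons
  for (i in seq_len(nrow(ex))) {
    if (ex$gene_id[i] == best$gene_id && ex$start[i] <= position &&
        ex$end[i] >= position) in_exon <- TRUE
  }
  list(region_class = if (in_exon) "exonic" else "intronic",
       gene_id = best$gene_id)
}

# --- exhaustive neighbor-joining oracle -----------------------------------
# Enumerate every unrooted binary topology on n tips (edge lists; tips are
# 1..n, internal nodes n+1, ...), least-squares fit branch lengths to a
# distance matrix, return the best-fitting topology's splits.

enumerate_topologies <- function(n) {
  stopifnot(n >= 3)
  start <- list(edges = rbind(c(n + 1, 1), c(n + 1, 2), c(n + 1, 3)),
                next_node = n + 2)
  trees <- list(start)
  for (tip in seq_len(n)[-(1:3)]) {
    trees <- unlist(lapply(trees, function(tr) {
      lapply(seq_len(nrow(tr$edges)), function(e) {
        w <- tr$next_node
        u <- tr$edges[e, 1]; v <- tr$edges[e, 2]
        edges <- rbind(tr$edges[-e, , drop = FALSE],
                       c(u, w), c(w, v), c(w, tip))
        list(edges = edges, next_node = w + 1)
      })
    }), recursive = FALSE)
  }
  lapply(trees, `[[`, "edges")
}

# Path-incidence matrix: row per tip pair (i < j), column per edge.
path_matrix <- function(edges, n) {
  nodes <- max(edges)
  adj <- vector("list", nodes)
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    adj[[u]] <- rbind(adj[[u]], c(v, e))
    adj[[v]] <- rbind(adj[[v]], c(u, e))
  }
  path_edges <- function(from, to) {
    # DFS carrying the edge trail
    stack <- list(list(node = from, trail = integer(0), prev = 0L))
    while (length(stack)) {
      st <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (st$node == to) return(st$trail)
      for (r in seq_len(nrow(adj[[st$node]]))) {
        nb <- adj[[st$node]][r, ]
        if (nb[1] != st$prev)
          stack[[length(stack) + 1L]] <-
            list(node = nb[1], trail = c(st$trail, nb[2]), prev = st$node)
      }
    }
    stop("no path")
  }
  pairs <- t(utils::combn(n, 2))
  A <- matrix(0, nrow(pairs), nrow(edges))
  for (r in seq_len(nrow(pairs)))
    A[r, path_edges(pairs[r, 1], pairs[r, 2])] <- 1
  A
}

topology_splits <- function(edges, n) {
  # bipartition of tips for each internal edge, as a canonical string
  nodes <- max(edges)
  adj <- vector("list", nodes)
  for (e in seq_len(nrow(edges))) {
    adj[[edges[e, 1]]] <- c(adj[[edges[e, 1]]], edges[e, 2])
    adj[[edges[e, 2]]] <- c(adj[[edges[e, 2]]], edges[e, 1])
  }
  tips_below <- function(node, parent) {
    out <- if (node <= n) node else integer(0)
    for (nb in adj[[node]]) {
      if (nb != parent) out <- c(out, tips_below(nb, node))
    }
    out
  }
  internal <- edges[edges[, 1] > n & edges[, 2] > n, , drop = FALSE]
  splits <- character(0)
  for (e in seq_len(nrow(internal))) {
    side <- sort(tips_below(internal[e, 2], internal[e, 1]))
    if (1 %in% side) side <- sort(setdiff(seq_len(n), side))
    splits <- c(splits, paste(side, collapse = ","))
  }
  sort(splits)
}

# Best least-squares topology for a distance matrix; returns its canonical
# split set and the minimum residual sum of squares.
nj_ls_oracle <- function(d) {
  n <- nrow(d)
  dv <- d[upper.tri(d)]  # combn order: (1,2),(1,3),...: row < col
  pairs <- t(utils::combn(n, 2))
  dv <- d[cbind(pairs[, 1], pairs[, 2])]
  best_sse <- Inf; best_splits <- NULL
  for (edges in enumerate_topologies(n)) {
    A <- path_matrix(edges, n)
    b <- tryCatch(solve(crossprod(A), crossprod(A, dv)),
                  error = function(e) NULL)
    if (is.null(b)) next
    sse <- sum((A %*% b - dv)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best_splits <- topology_splits(edges, n)
    }
  }
  list(splits = best_splits, sse = best_sse)
}

phylo_splits <- function(tree, ref = sort(tree$tip.label)) {
  # canonical split-string set of an unrooted phylo, indexed in `ref` order
  n <- length(tree$tip.label)
  idx <- stats::setNames(seq_along(ref), ref)
  internal <- which(tree$edge[, 2] > n)
  splits <- character(0)
  for (e in internal) {
    below <- ape::extract.clade(tree, tree$edge[e, 2])$tip.label
    side <- sort(unname(idx[below]))
    if (1 %in% side) side <- sort(setdiff(seq_len(n), side))
    if (length(side) >= 2 && length(side) <= n - 2)
      splits <- c(splits, paste(side, collapse = ","))
  }
  sort(unique(splits))
}

# Random additive distance matrix from a random unrooted binary tree.
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n, tip.label = paste0("t", 1:n)))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
  list(tree = tr, d = as.matrix(ape::cophenetic.phylo(tr)))
}

# --- fixture builders ------------------------------------------------------

tiny_geno <- function(calls, positions = NULL, chromosome = "chr1",
                      sets = NULL, sample_ids = NULL) {
  if (!is.matrix(calls)) calls <- matrix(calls, ncol = 1)
  m <- ncol(calls)
  if (is.null(positions)) positions <- seq_len(m) * 100L
  if (is.null(sample_ids)) sample_ids <- sprintf("s%02d", seq_len(nrow(calls)))
  snp_ids <- sprintf("m%02d", seq_len(m))
  rownames(calls) <- sample_ids
  colnames(calls) <- snp_ids
  genotype_matrix(calls,
                  data.frame(snp_id = snp_ids,
                             chromosome = rep_len(chromosome, m),
                             position = positions,
                             stringsAsFactors = FALSE),
                  sets)
}

# Two-SNP inbred panel realizing given haplotype counts
# (n00, n01, n10, n11 = counts of B-allele patterns at the two SNPs).
geno_from_hap_counts <- function(n00, n01, n10, n11, distance = 1000L) {
  h <- rbind(matrix(rep(c(0, 0), n00), ncol = 2, byrow = TRUE),
             matrix(rep(c(0, 1), n01), ncol = 2, byrow = TRUE),
             matrix(rep(c(1, 0), n10), ncol = 2, byrow = TRUE),
             matrix(rep(c(1, 1), n11), ncol = 2, byrow = TRUE))
  tiny_geno(2L * h, positions = c(100L, 100L + distance))
}

# Random annotation table: several chromosomes, mixed region classes,
# positions spanning gaps on both sides of the 10 kb threshold.
rand_annotation <- function(seed) {
  set.seed(seed)
  n_chrom <- sample(1:4, 1)
  rows <- list()
  for (c in seq_len(n_chrom)) {
    n <- sample(0:30, 1)
    if (n == 0) next
    pos <- sort(sample.int(2e5, n))
    rc <- sample(c("intergenic", "intronic", "exonic"), n, replace = TRUE)
    gid <- ifelse(rc == "intergenic", NA_character_,
                  paste0("g", c, "_", sample(1:8, n, replace = TRUE)))
    rows[[c]] <- data.frame(
      snp_id = sprintf("c%d_s%02d", c, seq_len(n)),
      chromosome = paste0("chr", c), position = pos,
      region_class = rc, gene_id = gid, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(snp_id = character(0), chromosome = character(0),
                      position = integer(0), region_class = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Random gene models (possibly overlapping genes) for classification tests.
rand_models <- function(seed, n_genes = 8, chrom_len = 10000) {
  set.seed(seed)
  genes <- list(); exons <- list()
  for (i in seq_len(n_genes)) {
    ch <- paste0("chr", sample(1:2, 1))
    start <- sample.int(chrom_len - 500, 1)
    end <- start + sample(100:1500, 1)
    gid <- sprintf("g%02d", i)
    genes[[i]] <- data.frame(gene_id = gid, chromosome = ch, strand = "+",
                             start = start, end = end,
                             stringsAsFactors = FALSE)
    k <- sample(1:3, 1)
    breaks <- sort(sample(start:end, 2 * k))
    exons[[i]] <- data.frame(gene_id = gid,
                             start = breaks[seq(1, 2 * k, 2)],
                             end = breaks[seq(2, 2 * k, 2)],
                             stringsAsFactors = FALSE)
  }
  structure(list(genes = do.call(rbind, genes),
                 exons = do.call(rbind, exons)),
            class = "gene_models")
}

small_sim <- function(seed, ...) {
  sim_config(n_chromosomes = 2, chrom_length_bp = 1e6,
             n_snps_per_chrom = 100,
             subpops = list(
               list(name = "tropical", n_samples = 60, n_founders = 8,
                    recomb_per_bp = 4e-6, n_generations = 10),
               list(name = "temperate", n_samples = 40, n_founders = 4,
                    recomb_per_bp = 1.5e-6, n_generations = 10)),
             seed = seed, ...)
}
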