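# Rogers genetic distances between lines, Saitou-Nei neighbor-joining with
# deterministic tie-breaking, and Newick export.

#' Rogers genetic distance between two samples
#'
#' Per locus, each individual is represented by its within-individual allele
#' frequency vector (homozygote: 1 for its allele; heterozygote: 1/2 each);
#' the locus distance is `sqrt(0.5 * sum_a (p_a - q_a)^2)` and the Rogers
#' distance is the average over loci, using only loci where both samples
#' have a non-missing call. For a biallelic SNP this reduces to the absolute
#' difference of the two B-allele dosages divided by 2.
#'
#' @param geno a [genotype_matrix()]
#' @param sample_x,sample_y sample ids
#' @return distance in `[0, 1]`
#' @export
rogers_distance <- function(geno, sample_x, sample_y) {
  x <- geno$calls[sample_x, ] / 2
  y <- geno$calls[sample_y, ] / 2
  shared <- !is.na(x) & !is.na(y)
  if (!any(shared))
    stop("undefined pair: no shared non-missing locus between ",
         sample_x, " and ", sample_y)
  mean(abs(x[shared] - y[shared]))
}

#' Rogers distance matrix over all sample pairs
#'
#' Vectorized pairwise-complete computation of [rogers_distance()] for every
#' pair of samples.
#'
#' @param geno a [genotype_matrix()]
#' @param snp_ids optional SNP subset (e.g. for haplotype-tagging markers)
#' @return symmetric matrix with zero diagonal, labelled by sample id
#' @export
rogers_distance_matrix <- function(geno, snp_ids = NULL) {
  calls <- geno$calls
  if (!is.null(snp_ids)) calls <- calls[, snp_ids, drop = FALSE]
  IA <- (!is.na(calls) & calls == CALL_HOM_A) + 0
  IH <- (!is.na(calls) & calls == CALL_HET) + 0
  IB <- (!is.na(calls) & calls == CALL_HOM_B) + 0
  # sum over shared loci of |x - y| with x, y in {0, 1/2, 1}:
  # 1 for opposite homozygotes, 1/2 for hom vs het.
  S <- tcrossprod(IA, IB)
  S <- S + t(S)
  H <- tcrossprod(IH, IA + IB)
  S <- S + 0.5 * (H + t(H))
  N <- tcrossprod(IA + IH + IB)
  if (any(N[upper.tri(N)] == 0)) {
    idx <- which(N == 0 & upper.tri(N), arr.ind = TRUE)[1, ]
    stop("undefined pair: no shared non-missing locus between ",
         rownames(calls)[idx[1]], " and ", rownames(calls)[idx[2]])
  }
  D <- S / N
  diag(D) <- 0
  dimnames(D) <- list(rownames(calls), rownames(calls))
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' The classical Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q_ij = (m - 2) d_ij - r_i - r_j` is joined, with ties broken by the
#' smallest (i, j) index pair so runs are reproducible. Limb lengths follow
#' the standard formulas and are clamped to zero when negative. The result
#' is unrooted, with a trifurcating final join.
#'
#' @param d symmetric distance matrix with labels (or a `dist`)
#' @return an [ape] `phylo` tree
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distance matrix must be non-negative")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  m <- nrow(d)
  if (m < 3) stop("need at least 3 labels")
  # each active node carries its Newick fragment; joins nest the fragments
  frag <- vapply(labels, quote_label, "")
  D <- unname(d)
  while (m > 3) {
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # smallest (i, j), i < j, among minima
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    frag_new <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], li, frag[j], lj)
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    frag <- c(frag[keep], frag_new)
    m <- m - 1L
  }
  l1 <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  l2 <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  l3 <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], l1, frag[2], l2, frag[3], l3)
  tr <- ape::read.tree(text = nwk)
  tr$tip.label <- unquote_label(tr$tip.label)
  tr
}

# ape::read.tree keeps Newick quoting in labels; undo it.
unquote_label <- function(x) {
  quoted <- grepl("^'.*'$", x)
  x[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[quoted]))
  x
}

quote_label <- function(x) {
  if (grepl("[][(),:;'[:space:]]", x))
    paste0("'", gsub("'", "''", x), "'")
  else x
}

#' Write a tree as Newick
#'
#' Serializes a `phylo` tree with branch lengths printed to 6 decimal
#' places and labels containing whitespace or Newick metacharacters quoted.
#'
#' @param tree an [ape] `phylo` object
#' @param path output file; `NULL` returns the string only
#' @return the Newick string, invisibly
#' @export
write_newick <- function(tree, path = NULL) {
  ntip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  len <- tree$edge.length
  serialize <- function(node, edge_idx) {
    if (node <= ntip) {
      lab <- quote_label(tree$tip.label[node])
    } else {
      kids <- children[[as.character(node)]]
      lab <- paste0("(", paste(vapply(kids, function(e)
        serialize(tree$edge[e, 2], e), ""), collapse = ","), ")")
    }
    if (is.null(edge_idx)) lab
    else sprintf("%s:%.6f", lab, len[edge_idx])
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  nwk <- paste0(serialize(root, NULL), ";")
  if (!is.null(path)) writeLines(nwk, path)
  invisible(nwk)
}

#' Deepest bipartition of an unrooted tree
#'
#' Returns the bipartition of the tip set induced by the internal edge that
#' contributes most to the total tip-to-tip path length, i.e. the edge
#' maximizing `branch length x n_left x n_right`. This is the principal
#' divergence of the tree - the natural candidate for its "two major
#' groups" split. (The raw longest internal edge is often a cherry of two
#' outlier samples; weighting by the tips on each side makes the choice a
#' measure of depth rather than of outlierness.)
#'
#' @param tree an [ape] `phylo` object
#' @return list with `left` and `right` (tip label character vectors),
#'   `length` (branch length of the splitting edge) and `score`
#'   (length x n_left x n_right)
#' @export
deepest_split <- function(tree) {
  ntip <- length(tree$tip.label)
  internal <- which(tree$edge[, 2] > ntip)
  if (!length(internal)) stop("tree has no internal edge")
  best <- NULL; best_score <- -Inf
  for (e in internal) {
    below <- ape::extract.clade(tree, tree$edge[e, 2])$tip.label
    score <- tree$edge.length[e] * length(below) * (ntip - length(below))
    if (score > best_score) {
      best_score <- score
      best <- list(left = below,
                   right = setdiff(tree$tip.label, below),
                   length = tree$edge.length[e], score = score)
    }
  }
  best
}
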