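# Pairwise linkage disequilibrium on inbred lines: R^2 from two-locus
# haplotype counts (phase observable on homozygotes), exact-test
# significance, per-chromosome significant-pair summaries and
# distance-binned decay curves with decay-distance estimation.

#' Minor allele frequency per SNP
#' @param geno a [genotype_matrix()]
#' @param samples sample ids or a set label (NULL = all)
#' @return named numeric vector of MAF (NA where all calls missing)
#' @export
maf <- function(geno, samples = NULL) {
  ids <- resolve_samples(geno, samples)
  cnt <- snp_counts(geno$calls[ids, , drop = FALSE])
  tot <- cnt[, 1] + cnt[, 2]
  out <- pmin(cnt[, 1], cnt[, 2]) / tot
  out[tot == 0] <- NA_real_
  stats::setNames(out, geno$snps$snp_id)
}

#' Filter SNPs on minor allele frequency
#'
#' Retains SNPs whose MAF is strictly greater than `threshold` within the
#' given sample subset; monomorphic and all-missing SNPs are excluded.
#'
#' @inheritParams maf
#' @param threshold MAF cutoff (strict `>`; default 0.05)
#' @return character vector of retained snp_ids
#' @export
maf_filter <- function(geno, threshold = 0.05, samples = NULL) {
  f <- maf(geno, samples)
  names(f)[!is.na(f) & f > threshold]
}

#' Two-sided exact test for a 2x2 table
#'
#' Fisher's exact probability: the sum, over all tables with the observed
#' margins, of hypergeometric probabilities not exceeding that of the
#' observed table (with a 1e-7 relative tolerance, as in
#' [stats::fisher.test()]). A table with an all-zero margin has p = 1.
#'
#' @param tab 2x2 matrix of non-negative counts, or a length-4 vector
#'   (a, b, c, d) filling the table by row
#' @return p-value in (0, 1]
#' @export
exact_test_p <- function(tab) {
  x <- as.vector(t(tab))
  if (length(x) != 4 || any(x < 0)) stop("need a 2x2 table of counts >= 0")
  fisher_p_vec(x[1], x[2], x[3], x[4])
}

# Vectorized two-sided Fisher p for tables [[a, b], [c, d]].
fisher_p_vec <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  out <- numeric(length(a))
  for (i in seq_along(a)) {
    if (m[i] + n[i] == 0 || m[i] == 0 || n[i] == 0 || k[i] == 0 ||
        k[i] == m[i] + n[i]) {
      out[i] <- 1
      next
    }
    supp <- max(0L, k[i] - n[i]):min(k[i], m[i])
    pr <- stats::dhyper(supp, m[i], n[i], k[i])
    pobs <- stats::dhyper(a[i], m[i], n[i], k[i])
    out[i] <- min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
  }
  out
}

#' Pairwise LD for all within-chromosome SNP pairs
#'
#' Two-locus haplotype counts are taken from samples homozygous and
#' non-missing at both SNPs (inbred lines, so phase is known; heterozygous
#' calls are excluded). With B-allele frequencies `p_i`, `p_j` and joint
#' `p_ij`, `D = p_ij - p_i p_j` and
#' `R^2 = D^2 / (p_i (1 - p_i) p_j (1 - p_j))`; significance is the
#' two-sided exact test on the 2x2 haplotype count table. Pairs with fewer
#' than `min_informative` informative samples, or with either SNP
#' monomorphic among them, are skipped (counts reported in attributes
#' `n_skipped_few` and `n_skipped_mono`). Only within-chromosome pairs are
#' considered.
#'
#' @param geno a [genotype_matrix()]
#' @param samples sample ids or a set label (NULL = all)
#' @param snp_ids SNP subset (e.g. from [maf_filter()]; NULL = all)
#' @param min_informative minimum informative sample count per pair
#' @param compute_p compute exact-test p-values (set `FALSE` to skip when
#'   only R^2 is needed)
#' @return data.frame: `snp_i`, `snp_j`, `chromosome`, `distance_bp`, `r2`,
#'   `p_value`, `n_informative`
#' @export
ld_pairs <- function(geno, samples = NULL, snp_ids = NULL,
                     min_informative = 10, compute_p = TRUE) {
  ids <- resolve_samples(geno, samples)
  snps <- geno$snps
  if (!is.null(snp_ids)) snps <- snps[snps$snp_id %in% snp_ids, , drop = FALSE]
  out <- list(); n_few <- 0L; n_mono <- 0L
  for (ch in unique(snps$chromosome)) {
    s <- snps[snps$chromosome == ch, , drop = FALSE]
    if (nrow(s) < 2) next
    calls <- geno$calls[ids, s$snp_id, drop = FALSE]
    A <- (!is.na(calls) & calls == CALL_HOM_A) + 0  # haplotype allele A
    B <- (!is.na(calls) & calls == CALL_HOM_B) + 0  # haplotype allele B
    nAA <- crossprod(A)        # [i, j]: count of (A at i, A at j)
    nAB <- crossprod(A, B)
    nBA <- t(nAB)
    nBB <- crossprod(B)
    ut <- upper.tri(nAA)
    a <- nAA[ut]; b <- nAB[ut]; c <- nBA[ut]; d <- nBB[ut]
    n <- a + b + c + d
    ii <- row(nAA)[ut]; jj <- col(nAA)[ut]
    few <- n < min_informative
    pBi <- (c + d) / n; pBj <- (b + d) / n
    mono <- !few & (pBi <= 0 | pBi >= 1 | pBj <= 0 | pBj >= 1)
    n_few <- n_few + sum(few); n_mono <- n_mono + sum(mono)
    keep <- !few & !mono
    if (!any(keep)) next
    a <- a[keep]; b <- b[keep]; c <- c[keep]; d <- d[keep]; n <- n[keep]
    pBi <- pBi[keep]; pBj <- pBj[keep]
    D <- d / n - pBi * pBj
    r2 <- D^2 / (pBi * (1 - pBi) * pBj * (1 - pBj))
    p <- if (compute_p) fisher_p_vec(a, b, c, d) else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      snp_i = s$snp_id[ii[keep]], snp_j = s$snp_id[jj[keep]],
      chromosome = ch,
      distance_bp = abs(s$position[jj[keep]] - s$position[ii[keep]]),
      r2 = pmin(r2, 1), p_value = p, n_informative = as.integer(n),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(snp_i = character(0), snp_j = character(0),
               chromosome = character(0), distance_bp = integer(0),
               r2 = numeric(0), p_value = numeric(0),
               n_informative = integer(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_skipped_few") <- n_few
  attr(res, "n_skipped_mono") <- n_mono
  res
}

#' LD between one pair of SNPs
#'
#' Single-pair convenience wrapper around the [ld_pairs()] computation.
#' Returns `NULL` (with a message) when the pair is uninformative: fewer
#' than `min_informative` doubly-homozygous samples or a SNP monomorphic
#' among them.
#'
#' @inheritParams ld_pairs
#' @param snp_i,snp_j snp_ids on the same chromosome
#' @return one-row data.frame as in [ld_pairs()], or `NULL`
#' @export
pairwise_r2 <- function(geno, snp_i, snp_j, samples = NULL,
                        min_informative = 10) {
  s <- geno$snps[match(c(snp_i, snp_j), geno$snps$snp_id), ]
  if (anyNA(s$snp_id)) stop("unknown snp_id")
  if (s$chromosome[1] != s$chromosome[2])
    stop("SNPs are on different chromosomes")
  res <- ld_pairs(geno, samples = samples, snp_ids = c(snp_i, snp_j),
                  min_informative = min_informative)
  if (!nrow(res)) {
    message("pair skipped: fewer than ", min_informative,
            " informative samples or monomorphic SNP")
    return(NULL)
  }
  res
}

#' Per-chromosome and overall LD summary
#'
#' The significant-pair summary behind per-chromosome LD comparison tables:
#' per chromosome and overall, the percentage of pairs significant at
#' `alpha`, and the percentage of pairs with `r2 > r2_cut` under both
#' denominators in use (all pairs, and significant pairs only). When a
#' chromosome has no significant pair the significant-pair-denominator
#' column is reported as 0 and flagged.
#'
#' @param pairs data.frame from [ld_pairs()]
#' @param alpha significance level (default 0.01)
#' @param r2_cut R^2 threshold (default 0.1)
#' @return data.frame: `chromosome`, `n_pairs`, `pct_sig`,
#'   `pct_sig_r2_all`, `pct_sig_r2_of_sig`, `no_sig_flag`; last row is
#'   `"All"`
#' @export
summarize_ld <- function(pairs, alpha = 0.01, r2_cut = 0.1) {
  if (!nrow(pairs)) stop("no LD pairs to summarize")
  one <- function(p, label) {
    sig <- p$p_value <= alpha
    hi <- sig & p$r2 > r2_cut
    data.frame(chromosome = label, n_pairs = nrow(p),
               pct_sig = 100 * mean(sig),
               pct_sig_r2_all = 100 * mean(hi),
               pct_sig_r2_of_sig = if (any(sig)) 100 * sum(hi) / sum(sig) else 0,
               no_sig_flag = !any(sig), stringsAsFactors = FALSE)
  }
  chroms <- unique(pairs$chromosome)
  rows <- lapply(chroms, function(ch)
    one(pairs[pairs$chromosome == ch, , drop = FALSE], ch))
  out <- rbind(do.call(rbind, rows), one(pairs, "All"))
  rownames(out) <- NULL
  out
}

DEFAULT_BIN_EDGES <- c(0, 1e3, 2e3, 5e3, 1e4, 2e4, 5e4, 1e5, 1e6, Inf)

#' Distance-binned LD decay curve and decay distance
#'
#' Pairs are assigned to half-open distance bins `(lo, hi]` and the mean
#' R^2 per bin is computed. The decay distance is the physical distance at
#' which mean R^2 first falls below `threshold`, linearly interpolated
#' between the centers of the last bin at or above the threshold and the
#' first bin below it (empty bins are skipped). If already below in the
#' first occupied bin the estimate is censored low; if never below,
#' censored high. The default bins are geometric (1, 2, 5, 10, 20, 50,
#' 100, 1000 kb, then open-ended); the unbounded last bin uses its lower
#' edge as center.
#'
#' @param pairs data.frame from [ld_pairs()]
#' @param bin_edges increasing bp bin edges starting at 0
#' @param threshold decay threshold on mean R^2 (default 0.1)
#' @return object of class `decay_curve`: list with `curve` (data.frame
#'   `bin_lo`, `bin_hi`, `center`, `mean_r2`, `n_pairs`),
#'   `decay_distance_bp` (NA when censored) and `censored` (one of
#'   `"none"`, `"low"`, `"high"`)
#' @export
decay_curve <- function(pairs, bin_edges = DEFAULT_BIN_EDGES,
                        threshold = 0.1) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  if (!nrow(pairs)) stop("no LD pairs")
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1]
  idx <- findInterval(pairs$distance_bp, bin_edges, left.open = TRUE,
                      rightmost.closed = FALSE)
  idx[idx < 1 | idx > length(lo)] <- NA
  mean_r2 <- vapply(seq_along(lo), function(b)
    if (any(idx == b, na.rm = TRUE))
      mean(pairs$r2[which(idx == b)]) else NA_real_, 0)
  n_pairs <- vapply(seq_along(lo), function(b)
    sum(idx == b, na.rm = TRUE), 0L)
  center <- ifelse(is.finite(hi), (lo + hi) / 2, lo)
  curve <- data.frame(bin_lo = lo, bin_hi = hi, center = center,
                      mean_r2 = mean_r2, n_pairs = n_pairs)
  occ <- which(!is.na(mean_r2))
  censored <- "none"; dist <- NA_real_
  below <- mean_r2[occ] < threshold
  if (!length(occ)) {
    censored <- "low"
  } else if (below[1]) {
    censored <- "low"
  } else if (!any(below)) {
    censored <- "high"
  } else {
    k <- which(below)[1]
    b_hi <- occ[k - 1]; b_lo <- occ[k]
    dist <- center[b_hi] + (center[b_lo] - center[b_hi]) *
      (mean_r2[b_hi] - threshold) / (mean_r2[b_hi] - mean_r2[b_lo])
  }
  structure(list(curve = curve, decay_distance_bp = dist,
                 censored = censored, threshold = threshold),
            class = "decay_curve")
}

#' Decay distance of a decay curve, with censoring mapped for comparison
#'
#' Returns the interpolated decay distance in bp; a curve censored low
#' (mean R^2 below the threshold already in the first occupied bin, i.e.
#' decay below the binning resolution) maps to 0 and a curve censored high
#' maps to `Inf`, so decay distances remain comparable across germplasm
#' sets whichever side of the resolution they fall on.
#'
#' @param x a [decay_curve()] object
#' @return numeric distance in bp (0 or `Inf` when censored)
#' @export
decay_distance <- function(x) {
  stopifnot(inherits(x, "decay_curve"))
  switch(x$censored, none = x$decay_distance_bp, low = 0, high = Inf)
}

#' @export
print.decay_curve <- function(x, ...) {
  cat("decay_curve:", sum(x$curve$n_pairs), "pairs in",
      sum(x$curve$n_pairs > 0), "occupied bins\n")
  if (x$censored == "none")
    cat(sprintf("  decay distance (mean R^2 < %.2g): %.0f bp\n",
                x$threshold, x$decay_distance_bp))
  else cat("  decay distance censored", x$censored, "\n")
  invisible(x)
}

#' Square R^2 and p matrices for one chromosome
#'
#' Numeric companion to triangular LD heatmaps: symmetric matrices of R^2
#' and p-values over the SNPs of one chromosome present in `pairs`.
#'
#' @param pairs data.frame from [ld_pairs()]
#' @param chromosome chromosome label
#' @return list with matrices `r2` and `p` (NA where a pair was skipped)
#' @export
ld_matrices <- function(pairs, chromosome) {
  p <- pairs[pairs$chromosome == chromosome, , drop = FALSE]
  if (!nrow(p)) stop("no pairs for chromosome ", chromosome)
  ids <- unique(c(p$snp_i, p$snp_j))
  r2m <- pm <- matrix(NA_real_, length(ids), length(ids),
                      dimnames = list(ids, ids))
  i <- match(p$snp_i, ids); j <- match(p$snp_j, ids)
  r2m[cbind(i, j)] <- r2m[cbind(j, i)] <- p$r2
  pm[cbind(i, j)] <- pm[cbind(j, i)] <- p$p_value
  diag(r2m) <- 1; diag(pm) <- 0
  list(r2 = r2m, p = pm)
}
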