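# Diversity statistics: allele frequencies, MAF, heterozygosity and the
# polymorphic information content (PIC), per SNP, per haplotype locus and
# aggregated by marker set x germplasm set.

#' Polymorphic information content
#'
#' `PIC = 1 - sum_j p_j^2 - sum_{j<k} 2 p_j^2 p_k^2` over the `n` alleles of
#' a marker. Computed through the algebraic identity
#' `sum_{j<k} 2 p_j^2 p_k^2 = (sum p^2)^2 - sum p^4`. A monomorphic marker
#' (one allele) has PIC 0; the biallelic maximum, at frequencies
#' (0.5, 0.5), is 0.375.
#'
#' @param freqs numeric vector of allele frequencies summing to 1
#' @return PIC value in `[0, 1)`
#' @export
pic <- function(freqs) {
  if (any(freqs < 0)) stop("negative allele frequency")
  if (abs(sum(freqs) - 1) > 1e-6)
    stop("allele frequencies must sum to 1 (got ", sum(freqs), ")")
  s2 <- sum(freqs^2)
  1 - s2 - (s2^2 - sum(freqs^4))
}

#' Allele frequencies and MAF at one locus
#'
#' For SNP calls (integer dosage coding) each homozygote contributes two
#' counts to its allele and each heterozygote one count to each allele. For
#' haplotype alleles (character strings) each non-missing sample contributes
#' one count. The MAF of a multi-allelic locus is the frequency of the
#' second most frequent allele.
#'
#' @param calls integer vector of SNP calls (0/1/2/NA) or character vector
#'   of haplotype alleles (`NA` = missing)
#' @return list with `freqs` (named, summing to 1), `maf`, `n_alleles` and
#'   `n` (non-missing sample count); `NULL` when every call is missing
#' @export
allele_frequencies <- function(calls) {
  if (is.numeric(calls) || is.integer(calls)) {
    calls <- calls[!is.na(calls)]
    if (!length(calls)) return(NULL)
    nA <- 2L * sum(calls == CALL_HOM_A) + sum(calls == CALL_HET)
    nB <- 2L * sum(calls == CALL_HOM_B) + sum(calls == CALL_HET)
    freqs <- c(A = nA, B = nB) / (nA + nB)
  } else {
    calls <- calls[!is.na(calls)]
    if (!length(calls)) return(NULL)
    tab <- table(calls)
    freqs <- sort(as.vector(tab) / sum(tab), decreasing = TRUE)
    names(freqs) <- names(sort(tab, decreasing = TRUE))
    return(list(freqs = freqs,
                maf = if (length(freqs) > 1) unname(freqs[2]) else 0,
                n_alleles = length(freqs), n = length(calls)))
  }
  present <- freqs[freqs > 0]
  list(freqs = freqs, maf = min(freqs), n_alleles = length(present),
       n = length(calls))
}

#' Heterozygosity of a SNP
#' @param calls integer vector of SNP calls (0/1/2/NA)
#' @return fraction of heterozygous calls among non-missing; `NA` if all
#'   calls are missing
#' @export
heterozygosity <- function(calls) {
  n <- sum(!is.na(calls))
  if (n == 0) return(NA_real_)
  sum(calls == CALL_HET, na.rm = TRUE) / n
}

# Vectorized per-SNP allele counts over a call matrix (samples x SNPs).
snp_counts <- function(calls) {
  nA <- 2L * colSums(calls == CALL_HOM_A, na.rm = TRUE) +
    colSums(calls == CALL_HET, na.rm = TRUE)
  nB <- 2L * colSums(calls == CALL_HOM_B, na.rm = TRUE) +
    colSums(calls == CALL_HET, na.rm = TRUE)
  cbind(nA = nA, nB = nB)
}

#' Per-SNP diversity table
#'
#' Allele frequencies, MAF, heterozygosity and PIC for every SNP, within an
#' optional sample subset. SNPs with no non-missing call in the subset are
#' skipped; their count is reported in attribute `n_skipped`.
#'
#' @param geno a [genotype_matrix()]
#' @param samples sample ids or a set label (NULL = all samples)
#' @param snp_ids SNPs to include (NULL = all)
#' @return data.frame: `snp_id`, `n`, `n_alleles`, `freq_a`, `maf`,
#'   `heterozygosity`, `pic`
#' @export
snp_diversity <- function(geno, samples = NULL, snp_ids = NULL) {
  ids <- resolve_samples(geno, samples)
  keep <- if (is.null(snp_ids)) geno$snps$snp_id else snp_ids
  calls <- geno$calls[ids, keep, drop = FALSE]
  cnt <- snp_counts(calls)
  tot <- cnt[, 1] + cnt[, 2]
  skip <- tot == 0
  p <- cnt[, 1] / tot
  q <- 1 - p
  s2 <- p^2 + q^2
  out <- data.frame(
    snp_id = keep,
    n = colSums(!is.na(calls)),
    n_alleles = (cnt[, 1] > 0) + (cnt[, 2] > 0),
    freq_a = p,
    maf = pmin(p, q),
    heterozygosity = colSums(calls == CALL_HET, na.rm = TRUE) /
      pmax(colSums(!is.na(calls)), 1L),
    pic = 1 - s2 - (s2^2 - (p^4 + q^4)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[!skip, , drop = FALSE]
  attr(out, "n_skipped") <- sum(skip)
  out
}

#' Per-locus diversity table for haplotype calls
#'
#' @param hap a [call_haplotypes()] object
#' @param samples sample ids to restrict to (NULL = all rows of the call
#'   matrix); set labels are resolved against `geno` when supplied
#' @param geno optional [genotype_matrix()] used to resolve a set label
#' @return data.frame: `locus_id`, `n`, `n_alleles`, `maf`, `pic`
#'   (heterozygosity of a haplotype locus is 0 by construction)
#' @export
haplotype_diversity <- function(hap, samples = NULL, geno = NULL) {
  rows <- rownames(hap$alleles)
  if (!is.null(samples)) {
    if (!is.null(geno)) samples <- resolve_samples(geno, samples)
    rows <- intersect(rows, samples)
  }
  am <- hap$alleles[rows, , drop = FALSE]
  res <- lapply(seq_len(ncol(am)), function(i) allele_frequencies(am[, i]))
  skip <- vapply(res, is.null, TRUE)
  out <- data.frame(
    locus_id = colnames(am)[!skip],
    n = vapply(res[!skip], `[[`, 0, "n"),
    n_alleles = vapply(res[!skip], `[[`, 0, "n_alleles"),
    maf = vapply(res[!skip], `[[`, 0, "maf"),
    pic = vapply(res[!skip], function(r) pic(r$freqs), 0),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_skipped") <- sum(skip)
  out
}

#' Diversity summary by marker set and germplasm set
#'
#' Recomputes allele frequencies within each germplasm set (and the entire
#' panel) for every SNP marker set and haplotype scheme supplied, then
#' averages: the machinery behind the classic marker-type x germplasm-set
#' PIC comparison tables. Loci with no non-missing call within a subset are
#' excluded from that subset's mean (counts reported via `n_loci`).
#'
#' @param geno a [genotype_matrix()]
#' @param marker_sets optional [build_marker_sets()] object (or named list of
#'   snp_id vectors); default: the single set `all`
#' @param haplotypes optional named list of [call_haplotypes()] objects,
#'   e.g. `list(slide3 = ..., kb10 = ..., gene = ...)`
#' @param germplasm_sets set labels to summarize separately (default: every
#'   label present); the entire panel is always included as `"entire"`
#' @return data.frame: `marker_set`, `germplasm_set`, `n_loci`,
#'   `allele_total`, `mean_n_alleles`, `mean_maf`, `mean_pic`
#' @export
summarize_diversity <- function(geno, marker_sets = NULL, haplotypes = NULL,
                                germplasm_sets = NULL) {
  if (is.null(marker_sets)) marker_sets <- list(all = geno$snps$snp_id)
  if (is.null(germplasm_sets))
    germplasm_sets <- unique(geno$samples$set_label)
  for (gs in germplasm_sets) {
    if (!any(geno$samples$set_label == gs))
      stop("empty germplasm set: ", gs)
  }
  subsets <- c(list(entire = geno$samples$sample_id),
               stats::setNames(lapply(germplasm_sets, function(gs)
                 geno$samples$sample_id[geno$samples$set_label == gs]),
                 germplasm_sets))
  rows <- list()
  for (ms in names(marker_sets)) {
    ids <- marker_sets[[ms]]
    if (!length(ids)) next
    for (gs in names(subsets)) {
      d <- snp_diversity(geno, samples = subsets[[gs]], snp_ids = ids)
      if (!nrow(d)) next
      rows[[length(rows) + 1L]] <- data.frame(
        marker_set = ms, germplasm_set = gs, n_loci = nrow(d),
        allele_total = sum(d$n_alleles),
        mean_n_alleles = mean(d$n_alleles),
        mean_maf = mean(d$maf), mean_pic = mean(d$pic),
        stringsAsFactors = FALSE)
    }
  }
  for (hs in names(haplotypes)) {
    for (gs in names(subsets)) {
      d <- haplotype_diversity(haplotypes[[hs]], samples = subsets[[gs]])
      if (!nrow(d)) next
      rows[[length(rows) + 1L]] <- data.frame(
        marker_set = hs, germplasm_set = gs, n_loci = nrow(d),
        allele_total = sum(d$n_alleles),
        mean_n_alleles = mean(d$n_alleles),
        mean_maf = mean(d$maf), mean_pic = mean(d$pic),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
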