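# The three haplotype windowing schemes: gene windows, disjoint 3-SNP sliding
# windows, and 10 kb proximity chains; plus per-sample haplotype calling
# under the all-or-nothing missing rule.

make_loci <- function(scheme, chromosome, members, positions, gene_id = NA) {
  data.frame(
    locus_id = sprintf("%s_%s_%d", scheme, chromosome, positions[1]),
    scheme = scheme, chromosome = chromosome,
    start = positions[1], end = positions[length(positions)],
    n_snps = length(members),
    gene_id = gene_id,
    members = I(list(members)),
    stringsAsFactors = FALSE)
}

sort_ann <- function(ann) {
  ann <- ann[snp_order(ann), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Gene-window haplotype loci
#'
#' One haplotype locus per distinct gene: all genic SNPs sharing a `gene_id`
#' form one locus, in genomic order. Single-SNP gene loci are returned too;
#' the subset with two or more member SNPs (the one used for haplotype
#' diversity comparison) is `loci[loci$n_snps >= 2, ]`.
#'
#' @param ann annotation data.frame with `region_class` and `gene_id` filled
#' @return data.frame of loci (`locus_id`, `scheme`, `chromosome`, `start`,
#'   `end`, `n_snps`, `gene_id`, list-column `members`)
#' @export
build_gene_windows <- function(ann) {
  ann <- sort_ann(ann)
  genic <- ann[!is.na(ann$gene_id) &
                 ann$region_class %in% c("exonic", "intronic"), , drop = FALSE]
  if (!nrow(genic)) return(empty_loci())
  parts <- split(genic, genic$gene_id)
  out <- do.call(rbind, lapply(parts, function(g)
    make_loci("gene", g$chromosome[1], g$snp_id, g$position, g$gene_id[1])))
  out <- out[order(chrom_rank(out$chromosome), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Disjoint 3-SNP sliding-window haplotype loci
#'
#' Per chromosome, every `window_size` consecutive SNPs form one locus,
#' starting from the first SNP, each SNP used in at most one locus. The
#' trailing `n mod window_size` SNPs of each chromosome stay unassigned and
#' are reported in attribute `unassigned`.
#'
#' @param ann annotation data.frame sorted by (chromosome, position)
#' @param window_size SNPs per window (default 3)
#' @return data.frame of loci with attribute `unassigned` (snp_ids)
#' @export
build_slide3_windows <- function(ann, window_size = 3L) {
  stopifnot(window_size >= 2)
  ann <- sort_ann(ann)
  loci <- list(); left <- character(0)
  for (ch in unique(ann$chromosome)) {
    a <- ann[ann$chromosome == ch, , drop = FALSE]
    k <- nrow(a) %/% window_size
    if (k > 0) {
      for (w in seq_len(k)) {
        idx <- ((w - 1L) * window_size + 1L):(w * window_size)
        loci[[length(loci) + 1L]] <-
          make_loci("slide3", ch, a$snp_id[idx], a$position[idx])
      }
    }
    if (nrow(a) %% window_size > 0)
      left <- c(left, a$snp_id[(k * window_size + 1L):nrow(a)])
  }
  out <- if (length(loci)) do.call(rbind, loci) else empty_loci()
  rownames(out) <- NULL
  attr(out, "unassigned") <- left
  out
}

#' 10 kb proximity-chain haplotype loci
#'
#' A SNP whose nearest same-chromosome neighbour is more than `threshold_bp`
#' away is excluded as an unlinked marker. The remaining SNPs chain
#' transitively: adjacent SNPs at a gap of at most `threshold_bp` join the
#' same locus, so every locus has at least two members, every within-locus
#' adjacent gap is `<= threshold_bp`, and consecutive loci are separated by
#' more than `threshold_bp`.
#'
#' @param ann annotation data.frame
#' @param threshold_bp chaining distance in bp (default 10000)
#' @return list with `loci` (data.frame) and `excluded` (snp_ids)
#' @export
build_kb10_windows <- function(ann, threshold_bp = 10000) {
  ann <- sort_ann(ann)
  loci <- list(); excluded <- character(0)
  for (ch in unique(ann$chromosome)) {
    a <- ann[ann$chromosome == ch, , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(diff(a$position) > threshold_bp)))
    for (g in split(seq_len(nrow(a)), grp)) {
      if (length(g) < 2) {
        excluded <- c(excluded, a$snp_id[g])
      } else {
        loci[[length(loci) + 1L]] <-
          make_loci("kb10", ch, a$snp_id[g], a$position[g])
      }
    }
  }
  out <- if (length(loci)) do.call(rbind, loci) else empty_loci()
  rownames(out) <- NULL
  list(loci = out, excluded = excluded)
}

empty_loci <- function() {
  data.frame(locus_id = character(0), scheme = character(0),
             chromosome = character(0), start = integer(0), end = integer(0),
             n_snps = integer(0), gene_id = character(0),
             members = I(list()), stringsAsFactors = FALSE)
}

#' Call per-sample haplotype alleles at multi-SNP loci
#'
#' A sample whose member-SNP calls are all homozygous yields the concatenated
#' allele string (one letter per SNP: `A` for hom A, `B` for hom B). Under
#' the all-or-nothing missing rule, any missing member call makes the whole
#' locus missing for that sample; a heterozygous member call does too, since
#' phase is not observable.
#'
#' @param loci a loci data.frame from one of the `build_*_windows()` builders
#' @param geno a [genotype_matrix()]
#' @return object of class `haplotype_calls`: list with `loci`, character
#'   matrix `alleles` (samples x loci, `NA` = missing) and `tables`
#'   (per-locus named allele counts)
#' @export
call_haplotypes <- function(loci, geno) {
  all_members <- unlist(loci$members)
  absent <- setdiff(all_members, geno$snps$snp_id)
  if (length(absent))
    stop("member SNP(s) absent from genotype matrix: ",
         paste(utils::head(absent, 5), collapse = ", "),
         if (length(absent) > 5) " ...")
  n <- n_samples(geno)
  alleles <- matrix(NA_character_, nrow = n, ncol = nrow(loci),
                    dimnames = list(geno$samples$sample_id, loci$locus_id))
  letter <- c("A", NA, "B")  # indexed by call + 1; het -> NA
  for (i in seq_len(nrow(loci))) {
    cc <- geno$calls[, loci$members[[i]], drop = FALSE]
    lm <- matrix(letter[cc + 1L], nrow = n)
    complete <- rowSums(is.na(lm)) == 0L
    if (any(complete))
      alleles[complete, i] <- apply(lm[complete, , drop = FALSE], 1,
                                    paste, collapse = "")
  }
  tables <- lapply(seq_len(nrow(loci)), function(i) {
    t <- table(alleles[, i])
    stats::setNames(as.integer(t), names(t))
  })
  names(tables) <- loci$locus_id
  structure(list(loci = loci, alleles = alleles, tables = tables),
            class = "haplotype_calls")
}

#' @export
print.haplotype_calls <- function(x, ...) {
  cat(sprintf("haplotype_calls: %d loci x %d samples (scheme: %s)\n",
              nrow(x$loci), nrow(x$alleles),
              paste(unique(x$loci$scheme), collapse = ",")))
  invisible(x)
}
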