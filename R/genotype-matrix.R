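#' @keywords internal
"_PACKAGE"

# Genotype calls are stored as the dosage of the alternate ("B") allele:
# 0 = homozygous A, 1 = heterozygous, 2 = homozygous B, NA = missing.
CALL_HOM_A <- 0L
CALL_HET <- 1L
CALL_HOM_B <- 2L

REGION_CLASSES <- c("intergenic", "exonic", "intronic", "unknown")

# Canonical chromosome ordering: numeric-looking labels (optionally prefixed
# "chr") sort numerically and before everything else; ties lexicographic.
chrom_rank <- function(chrom) {
  u <- unique(as.character(chrom))
  num <- suppressWarnings(as.numeric(sub("^chr", "", u, ignore.case = TRUE)))
  match(as.character(chrom), u[order(is.na(num), num, u)])
}

snp_order <- function(snps) order(chrom_rank(snps$chromosome), snps$position)

#' Assemble a genotype matrix object
#'
#' The central data container of the package: biallelic SNP calls for a panel
#' of (mostly homozygous) inbred lines, together with the SNP annotation and a
#' germplasm-set label per sample. Calls are coded as the dosage of the B
#' allele (0 = hom A, 1 = het, 2 = hom B, `NA` = missing). SNPs are
#' canonicalized to (chromosome, position) order; positions must be strictly
#' increasing within a chromosome.
#'
#' @param calls integer matrix, samples x SNPs, values in \{0, 1, 2, NA\};
#'   rownames are sample ids, colnames are SNP ids matching `snps$snp_id`.
#' @param snps data.frame with columns `snp_id`, `chromosome`, `position` and
#'   optionally `region_class` (one of intergenic/exonic/intronic/unknown)
#'   and `gene_id`.
#' @param sets optional germplasm-set assignment: a named character vector
#'   (names are sample ids) or a data.frame with columns `sample_id`,
#'   `set_label`. Defaults to a single set `"all"`.
#' @return an object of class `genotype_matrix` with elements `calls`,
#'   `snps` and `samples`.
#' @export
genotype_matrix <- function(calls, snps, sets = NULL) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("`calls` must have sample rownames and SNP colnames")
  bad <- calls[!is.na(calls) & !(calls %in% c(0L, 1L, 2L))]
  if (length(bad)) stop("calls must be 0, 1, 2 or NA; found: ",
                        paste(unique(bad), collapse = ", "))
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  req <- c("snp_id", "chromosome", "position")
  if (!all(req %in% names(snps)))
    stop("`snps` needs columns: ", paste(req, collapse = ", "))
  if (is.null(snps$region_class)) snps$region_class <- "unknown"
  if (is.null(snps$gene_id)) snps$gene_id <- NA_character_
  snps$chromosome <- as.character(snps$chromosome)
  snps$position <- as.integer(snps$position)
  if (any(snps$position < 1)) stop("SNP positions must be >= 1")
  if (anyDuplicated(snps$snp_id)) {
    stop("duplicate snp_id: ",
         paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  }
  key <- paste(snps$chromosome, snps$position)
  if (anyDuplicated(key)) {
    stop("duplicate (chromosome, position): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  if (!setequal(colnames(calls), snps$snp_id))
    stop("colnames(calls) must match snps$snp_id")
  ord <- snp_order(snps)
  snps <- snps[ord, , drop = FALSE]
  rownames(snps) <- NULL
  calls <- calls[, snps$snp_id, drop = FALSE]

  ids <- rownames(calls)
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  if (is.null(sets)) {
    samples <- data.frame(sample_id = ids, set_label = "all",
                          stringsAsFactors = FALSE)
  } else {
    if (is.data.frame(sets)) {
      sets <- stats::setNames(as.character(sets$set_label), sets$sample_id)
    }
    if (!all(ids %in% names(sets)))
      stop("missing set label for sample(s): ",
           paste(setdiff(ids, names(sets)), collapse = ", "))
    samples <- data.frame(sample_id = ids,
                          set_label = unname(sets[ids]),
                          stringsAsFactors = FALSE)
  }
  structure(list(calls = calls, snps = snps, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$snps$chromosome))))
  tab <- table(x$samples$set_label)
  cat("  sets:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  missing: %.2f%%  het: %.2f%%\n",
              100 * mean(is.na(x$calls)),
              100 * mean(x$calls == CALL_HET, na.rm = TRUE)))
  invisible(x)
}

#' Number of samples / SNPs in a genotype matrix
#' @param geno a `genotype_matrix`
#' @return an integer count
#' @export
n_samples <- function(geno) nrow(geno$calls)

#' @rdname n_samples
#' @export
n_snps <- function(geno) ncol(geno$calls)

#' Subset a genotype matrix
#'
#' @param geno a `genotype_matrix`
#' @param samples sample ids, or a germplasm-set label, to keep (NULL = all)
#' @param snps SNP ids to keep (NULL = all)
#' @return a `genotype_matrix`
#' @export
subset_genotypes <- function(geno, samples = NULL, snps = NULL) {
  keep_s <- resolve_samples(geno, samples)
  keep_m <- if (is.null(snps)) geno$snps$snp_id else {
    miss <- setdiff(snps, geno$snps$snp_id)
    if (length(miss)) stop("unknown SNP id(s): ", paste(miss, collapse = ", "))
    geno$snps$snp_id[geno$snps$snp_id %in% snps]
  }
  genotype_matrix(geno$calls[keep_s, keep_m, drop = FALSE],
                  geno$snps[geno$snps$snp_id %in% keep_m, , drop = FALSE],
                  stats::setNames(geno$samples$set_label, geno$samples$sample_id)[keep_s])
}

# Resolve a `samples` argument: NULL (all), a set label, or explicit ids.
resolve_samples <- function(geno, samples) {
  ids <- geno$samples$sample_id
  if (is.null(samples)) return(ids)
  if (length(samples) == 1 && samples %in% geno$samples$set_label &&
      !(samples %in% ids)) {
    return(ids[geno$samples$set_label == samples])
  }
  miss <- setdiff(samples, ids)
  if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  ids[ids %in% samples]
}

#' Germplasm-set labels of a genotype matrix
#' @param geno a `genotype_matrix`
#' @return named character vector, sample id -> set label
#' @export
set_labels <- function(geno) {
  stats::setNames(geno$samples$set_label, geno$samples$sample_id)
}
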