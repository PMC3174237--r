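# Readers and writers for the standard plain-text formats: VCF 4.x (GT only),
# HapMap-like TSV, SNP annotation TSV, sample-set TSV and GFF3 gene models.

#' Read a genotype matrix from VCF or HapMap-like TSV
#'
#' VCF records are restricted to biallelic sites; multiallelic records are
#' excluded with a per-file report (count in attribute `n_multiallelic` and a
#' message). GT values `0/0`, `0/1` (or `1/0`), `1/1` and `./.` map to
#' hom A, het, hom B and missing; phased separators are accepted. The
#' HapMap-like TSV has one row per SNP with columns `snp_id`, `chromosome`,
#' `position`, then one call per sample: `A` (hom A), `B` (hom B), `H`
#' (het), `N` (missing).
#'
#' @param path input file
#' @param format `"vcf"` or `"hapmap_tsv"`
#' @param sets optional sample-set assignment (path to a sample-set TSV, a
#'   named vector or a data.frame as in [genotype_matrix()])
#' @return a [genotype_matrix()]
#' @export
read_genotypes <- function(path, format = c("vcf", "hapmap_tsv"), sets = NULL) {
  format <- match.arg(format)
  if (is.character(sets) && length(sets) == 1 && file.exists(sets))
    sets <- read_sample_sets(sets)
  if (format == "vcf") read_genotypes_vcf(path, sets)
  else read_genotypes_hapmap(path, sets)
}

read_genotypes_vcf <- function(path, sets = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  n_multi <- sum(!bi)
  if (n_multi > 0) {
    message(n_multi, " multiallelic record(s) excluded")
    v <- v[bi, ]
  }
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  blank <- is.na(ids) | ids == "." | ids == ""
  ids[blank] <- paste0(fix[blank, "CHROM"], "_", fix[blank, "POS"])
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  calls <- matrix(unname(code[gt]), nrow = nrow(gt))  # anything else -> NA
  rownames(calls) <- ids
  colnames(calls) <- colnames(gt)
  snps <- data.frame(snp_id = ids, chromosome = fix[, "CHROM"],
                     position = as.integer(fix[, "POS"]),
                     stringsAsFactors = FALSE)
  out <- genotype_matrix(t(calls), snps, sets)
  attr(out, "n_multiallelic") <- n_multi
  out
}

read_genotypes_hapmap <- function(path, sets = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("snp_id", "chromosome", "position")
  if (!all(req %in% names(df)[1:3]))
    stop("hapmap_tsv must start with columns: ", paste(req, collapse = ", "))
  samp <- names(df)[-(1:3)]
  if (!length(samp)) stop("hapmap_tsv has no sample columns")
  code <- c(A = 0L, H = 1L, B = 2L, N = NA_integer_)
  raw <- as.matrix(df[, -(1:3), drop = FALSE])
  bad <- setdiff(unique(as.vector(raw)), names(code))
  if (length(bad)) stop("unknown call token(s): ", paste(bad, collapse = ", "))
  calls <- matrix(code[raw], nrow = nrow(raw))
  snps <- data.frame(snp_id = df$snp_id, chromosome = as.character(df$chromosome),
                     position = as.integer(df$position), stringsAsFactors = FALSE)
  calls <- t(calls)
  rownames(calls) <- samp
  colnames(calls) <- snps$snp_id
  genotype_matrix(calls, snps, sets)
}

#' Write a genotype matrix to VCF or HapMap-like TSV
#'
#' The VCF writer emits a minimal VCF 4.2 with GT only; the abstract A and B
#' alleles are written as REF `A`, ALT `C`. The HapMap-like writer uses the
#' `A`/`B`/`H`/`N` call letters understood by [read_genotypes()].
#'
#' @param geno a [genotype_matrix()]
#' @param path output file
#' @param format `"vcf"` or `"hapmap_tsv"`
#' @return `path`, invisibly
#' @export
write_genotypes <- function(geno, path, format = c("vcf", "hapmap_tsv")) {
  format <- match.arg(format)
  if (format == "vcf") write_genotypes_vcf(geno, path)
  else write_genotypes_hapmap(geno, path)
  invisible(path)
}

write_genotypes_vcf <- function(geno, path) {
  gt_str <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = n_snps(geno), ncol = n_samples(geno))
  calls_t <- t(geno$calls)
  ok <- !is.na(calls_t)
  gt[ok] <- gt_str[calls_t[ok] + 1L]
  body <- paste(geno$snps$chromosome, geno$snps$position, geno$snps$snp_id,
                "A", "C", ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##source=haplodiv",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", geno$samples$sample_id),
                    collapse = "\t"))
  writeLines(c(header, body), path)
}

write_genotypes_hapmap <- function(geno, path) {
  letters_ <- c("A", "H", "B")
  m <- matrix("N", nrow = n_snps(geno), ncol = n_samples(geno))
  calls_t <- t(geno$calls)
  ok <- !is.na(calls_t)
  m[ok] <- letters_[calls_t[ok] + 1L]
  df <- data.frame(snp_id = geno$snps$snp_id,
                   chromosome = geno$snps$chromosome,
                   position = geno$snps$position, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(m, stringsAsFactors = FALSE))
  names(df)[-(1:3)] <- geno$samples$sample_id
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write a SNP annotation table
#'
#' TSV with columns `snp_id`, `chromosome`, `position`, `region_class`,
#' `gene_id`. Region classes are normalized case-insensitively to
#' intergenic/exonic/intronic/unknown; an unknown token is an error naming
#' the offending row. `gene_id` must be present exactly for genic
#' (exonic/intronic) SNPs.
#'
#' @param path TSV file
#' @param ann annotation data.frame (for the writer)
#' @return data.frame of SNP annotations
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  req <- c("snp_id", "chromosome", "position", "region_class")
  if (!all(req %in% names(df)))
    stop("annotation TSV needs columns: ", paste(req, collapse = ", "))
  if (is.null(df$gene_id)) df$gene_id <- NA_character_
  df$chromosome <- as.character(df$chromosome)
  df$region_class <- tolower(trimws(df$region_class))
  bad <- which(!(df$region_class %in% REGION_CLASSES))
  if (length(bad))
    stop("unknown region_class in row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(df$region_class[bad]), collapse = ", "))
  if (any(df$position < 1))
    stop("position must be >= 1 (row(s) ",
         paste(which(df$position < 1), collapse = ", "), ")")
  genic <- df$region_class %in% c("exonic", "intronic")
  bad <- which(genic != !is.na(df$gene_id))
  if (length(bad))
    stop("gene_id must be present exactly for exonic/intronic SNPs; row(s) ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(df$snp_id))
    stop("duplicate snp_id: ",
         paste(unique(df$snp_id[duplicated(df$snp_id)]), collapse = ", "))
  df <- df[snp_order(df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_annotation
#' @export
write_annotation <- function(ann, path) {
  cols <- c("snp_id", "chromosome", "position", "region_class", "gene_id")
  utils::write.table(ann[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a sample-to-germplasm-set table
#' @param path TSV with columns `sample_id`, `set_label`
#' @param sets named character vector or data.frame (for the writer)
#' @return named character vector, sample id -> set label
#' @export
read_sample_sets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "set_label") %in% names(df)))
    stop("sample-set TSV needs columns sample_id, set_label")
  stats::setNames(as.character(df$set_label), df$sample_id)
}

#' @rdname read_sample_sets
#' @export
write_sample_sets <- function(sets, path) {
  if (is.data.frame(sets))
    sets <- stats::setNames(as.character(sets$set_label), sets$sample_id)
  utils::write.table(data.frame(sample_id = names(sets),
                                set_label = unname(sets)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

gff_attr <- function(attributes, key) {
  vapply(strsplit(as.character(attributes), ";"), function(fields) {
    fields <- trimws(fields)
    hit <- grep(paste0("^", key, "="), fields, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA_character_
  }, character(1))
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene` and `exon` features; exon `Parent` attributes may reference
#' the gene directly or an mRNA/transcript whose `Parent` is the gene. Exons
#' of one gene are merged into a sorted, non-overlapping gene-level exon
#' union (closed intervals, 1-based). An exon whose parent cannot be
#' resolved, or that lies outside its gene span, is an error.
#'
#' @param path GFF3 file
#' @return object of class `gene_models`: list with data.frames `genes`
#'   (`gene_id`, `chromosome`, `strand`, `start`, `end`) and `exons`
#'   (`gene_id`, `start`, `end`)
#' @export
read_gene_models <- function(path) {
  g <- ape::read.gff(path, na.strings = c(".", "?"), GFF3 = TRUE)
  g$type <- as.character(g$type)
  genes <- g[g$type == "gene", , drop = FALSE]
  if (!nrow(genes)) stop("no gene features in ", path)
  gene_id <- gff_attr(genes$attributes, "ID")
  if (anyNA(gene_id)) stop("gene feature without ID attribute")
  if (any(genes$start > genes$end)) stop("gene with start > end")
  genes_df <- data.frame(gene_id = gene_id,
                         chromosome = as.character(genes$seqid),
                         strand = as.character(genes$strand),
                         start = genes$start, end = genes$end,
                         stringsAsFactors = FALSE)

  # map transcript-level IDs down to their gene
  tx <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  tx_map <- stats::setNames(gff_attr(tx$attributes, "Parent"),
                            gff_attr(tx$attributes, "ID"))

  ex <- g[g$type == "exon", , drop = FALSE]
  exons_df <- data.frame(gene_id = character(0), start = integer(0),
                         end = integer(0), stringsAsFactors = FALSE)
  if (nrow(ex)) {
    parent <- gff_attr(ex$attributes, "Parent")
    # multiple parents (comma-separated): take each in turn
    parent1 <- vapply(strsplit(parent, ","), `[`, "", 1)
    resolved <- ifelse(parent1 %in% genes_df$gene_id, parent1,
                       unname(tx_map[parent1]))
    orphan <- is.na(resolved) | !(resolved %in% genes_df$gene_id)
    if (any(orphan))
      stop("orphan exon(s): Parent not resolvable to a gene (",
           paste(unique(parent1[orphan]), collapse = ", "), ")")
    exons_df <- data.frame(gene_id = resolved, start = ex$start, end = ex$end,
                           stringsAsFactors = FALSE)
    gspan <- genes_df[match(exons_df$gene_id, genes_df$gene_id), ]
    out_of_span <- exons_df$start < gspan$start | exons_df$end > gspan$end
    if (any(out_of_span))
      stop("exon outside gene span for gene(s): ",
           paste(unique(exons_df$gene_id[out_of_span]), collapse = ", "))
    exons_df <- do.call(rbind, lapply(split(exons_df, exons_df$gene_id),
                                      merge_exons))
    rownames(exons_df) <- NULL
  }
  structure(list(genes = genes_df, exons = exons_df), class = "gene_models")
}

# Merge overlapping closed intervals of one gene into a sorted union.
merge_exons <- function(ex) {
  ex <- ex[order(ex$start, ex$end), , drop = FALSE]
  starts <- ex$start[1]; ends <- ex$end[1]
  for (i in seq_len(nrow(ex))[-1]) {
    k <- length(starts)
    if (ex$start[i] <= ends[k]) {
      ends[k] <- max(ends[k], ex$end[i])
    } else {
      starts <- c(starts, ex$start[i]); ends <- c(ends, ex$end[i])
    }
  }
  data.frame(gene_id = ex$gene_id[1], start = starts, end = ends,
             stringsAsFactors = FALSE)
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exon intervals on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons),
              length(unique(x$genes$chromosome))))
  invisible(x)
}
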