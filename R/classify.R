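# Region classification of SNPs against gene models, and the marker-set
# partition (all / intergenic / intragenic / intronic / exonic) used for
# comparative diversity.

#' Classify a single position against gene models
#'
#' A position inside any exon interval of its assigned gene is `exonic`;
#' inside the gene span but no exon, `intronic`; outside every gene span,
#' `intergenic`. When a position falls in several overlapping genes it is
#' assigned to the gene whose span starts first (ties broken by the
#' lexicographically smaller `gene_id`). Strand is ignored; intervals are
#' closed and 1-based. An empty gene list yields `intergenic`.
#'
#' @param chromosome chromosome label
#' @param position 1-based bp coordinate
#' @param models a [read_gene_models()] object
#' @return list with `region_class` and `gene_id` (`NA` if intergenic)
#' @export
classify_snp <- function(chromosome, position, models) {
  g <- models$genes
  hit <- which(g$chromosome == chromosome & g$start <= position &
                 g$end >= position)
  if (!length(hit))
    return(list(region_class = "intergenic", gene_id = NA_character_))
  hit <- hit[order(g$start[hit], g$gene_id[hit])][1]
  gid <- g$gene_id[hit]
  ex <- models$exons
  in_exon <- any(ex$gene_id == gid & ex$start <= position & ex$end >= position)
  list(region_class = if (in_exon) "exonic" else "intronic", gene_id = gid)
}

#' Classify all SNPs of an annotation table
#'
#' Fills `region_class` and `gene_id` for every row from the gene models,
#' overwriting any previous values.
#'
#' @param ann annotation data.frame (`snp_id`, `chromosome`, `position`, ...)
#' @param models a [read_gene_models()] object
#' @return the annotation with `region_class` and `gene_id` assigned
#' @export
classify_snps <- function(ann, models) {
  res <- mapply(function(ch, pos) classify_snp(ch, pos, models),
                ann$chromosome, ann$position, SIMPLIFY = FALSE)
  ann$region_class <- vapply(res, `[[`, "", "region_class")
  ann$gene_id <- vapply(res, function(r)
    if (is.na(r$gene_id)) NA_character_ else r$gene_id, "")
  ann
}

#' Build the five comparative marker sets
#'
#' Partitions annotated SNPs into the marker sets used throughout the
#' diversity comparison: `all`, `intergenic`, `intragenic` (= intronic
#' union exonic), `intronic` and `exonic`.
#'
#' @param ann annotation data.frame with `region_class` filled
#' @param allow_unknown drop SNPs with `region_class == "unknown"` (with a
#'   reported count) instead of erroring
#' @return object of class `marker_sets`: named list of snp_id vectors with
#'   attribute `n_dropped`
#' @export
build_marker_sets <- function(ann, allow_unknown = FALSE) {
  unknown <- ann$region_class == "unknown" | is.na(ann$region_class)
  if (any(unknown)) {
    if (!allow_unknown)
      stop(sum(unknown), " SNP(s) with unknown region_class ",
           "(set allow_unknown = TRUE to drop them)")
    message(sum(unknown), " SNP(s) with unknown region_class dropped")
    ann <- ann[!unknown, , drop = FALSE]
  }
  sets <- list(
    all        = ann$snp_id,
    intergenic = ann$snp_id[ann$region_class == "intergenic"],
    intragenic = ann$snp_id[ann$region_class %in% c("intronic", "exonic")],
    intronic   = ann$snp_id[ann$region_class == "intronic"],
    exonic     = ann$snp_id[ann$region_class == "exonic"])
  if (!length(sets$intragenic))
    warning("intragenic marker set is empty")
  structure(sets, class = "marker_sets", n_dropped = sum(unknown))
}

#' @export
print.marker_sets <- function(x, ...) {
  cat("marker_sets:",
      paste(sprintf("%s=%d", names(x), lengths(x)), collapse = ", "), "\n")
  if (attr(x, "n_dropped") > 0)
    cat("  (", attr(x, "n_dropped"), "unknown SNPs dropped )\n")
  invisible(x)
}
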