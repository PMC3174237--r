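# One-shot orchestration: simulate (or read) -> classify -> haplotype
# windows -> diversity -> structure -> LD, with staged TSV outputs and a
# plain-text run report.

#' Run the full comparative diversity / LD pipeline
#'
#' The configuration is a YAML file or an equivalent nested list with
#' exactly one of two top-level blocks: `simulate` (fields of
#' [sim_config()]) or `inputs` (`genotypes` path, `format`, optional
#' `annotation`, `gene_models`, `sample_sets` paths), plus optional blocks
#' `windows` (`kb10_threshold_bp`, `slide_window_size`), `ld` (`maf`,
#' `alpha`, `r2_cut`, `min_informative`), and top-level `out_dir` and
#' `seed`. Each stage writes its tables under `out_dir` and the run ends
#' with a `run_report.txt` echoing every parameter; identical config and
#' seed give identical outputs. A stage failure aborts with the stage name
#' and leaves a `FAILED` marker file.
#'
#' @param config path to a YAML config or a named list
#' @param out_dir output directory (overrides the config's `out_dir`)
#' @return invisibly, a list with the main result objects and file paths
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp)
    stop("config must have exactly one of the blocks 'simulate' or 'inputs'")
  out_dir <- out_dir %||% config$out_dir %||% stop("no out_dir given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  cfg_echo <- config
  cfg_echo$out_dir <- NULL  # environment-specific; keep reports comparable
  report <- c(sprintf("haplodiv %s run report",
                      as.character(utils::packageVersion("haplodiv"))),
              paste0("config: ", paste(utils::capture.output(
                utils::str(cfg_echo, give.head = FALSE)), collapse = " ")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                 failed_marker)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  w <- config$windows %||% list()
  ldp <- config$ld %||% list()
  kb10_thr <- w$kb10_threshold_bp %||% 10000
  slide_k <- w$slide_window_size %||% 3L
  maf_thr <- ldp$maf %||% 0.05
  alpha <- ldp$alpha %||% 0.01
  r2_cut <- ldp$r2_cut %||% 0.1
  min_inf <- ldp$min_informative %||% 10

  # stage 1: data
  geno <- stage("data", {
    if (has_sim) {
      sim_args <- config$simulate
      if (!is.null(config$seed)) sim_args$seed <- config$seed
      if (!is.null(sim_args$subpops))
        sim_args$subpops <- lapply(sim_args$subpops, as.list)
      cfg <- do.call(sim_config, sim_args)
      write_truth(cfg, file.path(out_dir, "sim_truth.tsv"))
      g <- simulate_genotypes(cfg)
      write_genotypes(g, file.path(out_dir, "genotypes.vcf"), "vcf")
      write_sample_sets(set_labels(g), file.path(out_dir, "sample_sets.tsv"))
      g
    } else {
      inp <- config$inputs
      if (is.null(inp$genotypes)) stop("inputs block needs 'genotypes'")
      read_genotypes(inp$genotypes, inp$format %||% "vcf",
                     sets = inp$sample_sets)
    }
  })
  report <- c(report, "", "[data]",
              sprintf("samples: %d  snps: %d", n_samples(geno), n_snps(geno)),
              sprintf("sets: %s", paste(sprintf("%s=%d",
                names(table(geno$samples$set_label)),
                table(geno$samples$set_label)), collapse = " ")))

  # stage 2: classification / marker sets
  ann <- geno$snps
  msets <- stage("classify", {
    if (has_inp && !is.null(config$inputs$annotation)) {
      ann <- read_annotation(config$inputs$annotation)
    }
    if (has_inp && !is.null(config$inputs$gene_models)) {
      ann <- classify_snps(ann, read_gene_models(config$inputs$gene_models))
      write_annotation(ann, file.path(out_dir, "classified.tsv"))
    }
    if (all(ann$region_class == "unknown")) {
      list(all = ann$snp_id)
    } else {
      build_marker_sets(ann, allow_unknown = TRUE)
    }
  })
  report <- c(report, "", "[classify]",
              paste(sprintf("%s=%d", names(msets), lengths(msets)),
                    collapse = "  "))

  # stage 3: haplotype windows + calls
  haps <- stage("haplotypes", {
    out <- list()
    s3 <- build_slide3_windows(ann, slide_k)
    out$slide3 <- call_haplotypes(s3, geno)
    k10 <- build_kb10_windows(ann, kb10_thr)
    if (nrow(k10$loci)) out$kb10 <- call_haplotypes(k10$loci, geno)
    gw <- build_gene_windows(ann)
    gw2 <- gw[gw$n_snps >= 2, , drop = FALSE]
    if (nrow(gw2)) out$gene <- call_haplotypes(gw2, geno)
    write_loci <- function(loci, path) {
      df <- loci[, c("locus_id", "scheme", "chromosome", "start", "end",
                     "n_snps")]
      df$members <- vapply(loci$members, paste, "", collapse = ",")
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    write_loci(s3, file.path(out_dir, "loci_slide3.tsv"))
    write_loci(k10$loci, file.path(out_dir, "loci_kb10.tsv"))
    write_loci(gw, file.path(out_dir, "loci_gene.tsv"))
    attr(out, "counts") <- c(
      slide3 = nrow(s3), slide3_unassigned = length(attr(s3, "unassigned")),
      kb10 = nrow(k10$loci), kb10_excluded = length(k10$excluded),
      gene = nrow(gw), gene_multi = nrow(gw2))
    out
  })
  cnt <- attr(haps, "counts")
  report <- c(report, "", "[haplotypes]",
              paste(sprintf("%s=%d", names(cnt), cnt), collapse = "  "))

  # stage 4: diversity
  div <- stage("diversity", {
    d <- summarize_diversity(geno, msets, haplotypes = haps)
    utils::write.table(d, file.path(out_dir, "diversity_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    d
  })
  ent <- div[div$germplasm_set == "entire", ]
  report <- c(report, "", "[diversity]",
              sprintf("%s: n_loci=%d mean_pic=%.3f", ent$marker_set,
                      ent$n_loci, ent$mean_pic))

  # stage 5: structure
  tree <- stage("structure", {
    D <- rogers_distance_matrix(geno)
    utils::write.table(round(D, 6), file.path(out_dir, "rogers_dist.tsv"),
                       sep = "\t", quote = FALSE)
    tr <- neighbor_joining(D)
    write_newick(tr, file.path(out_dir, "nj_tree.nwk"))
    tr
  })
  report <- c(report, "", "[structure]",
              sprintf("NJ tree: %d tips, written to nj_tree.nwk",
                      length(tree$tip.label)))

  # stage 6: LD per germplasm set (and entire panel)
  ld <- stage("ld", {
    sets <- unique(geno$samples$set_label)
    groups <- c(list(entire = NULL),
                stats::setNames(as.list(sets), sets))
    res <- list()
    for (gs in names(groups)) {
      keep <- maf_filter(geno, maf_thr, samples = groups[[gs]])
      pairs <- ld_pairs(geno, samples = groups[[gs]], snp_ids = keep,
                        min_informative = min_inf)
      if (!nrow(pairs)) next
      summ <- summarize_ld(pairs, alpha, r2_cut)
      dec <- decay_curve(pairs, threshold = r2_cut)
      utils::write.table(pairs,
                         file.path(out_dir, paste0("ld_pairs_", gs, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(summ,
                         file.path(out_dir, paste0("ld_summary_", gs, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(dec$curve,
                         file.path(out_dir, paste0("ld_decay_", gs, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res[[gs]] <- list(n_snps = length(keep), summary = summ, decay = dec)
    }
    res
  })
  for (gs in names(ld)) {
    all_row <- ld[[gs]]$summary[ld[[gs]]$summary$chromosome == "All", ]
    dd <- ld[[gs]]$decay
    report <- c(report, "", sprintf("[ld %s]", gs),
                sprintf("snps(maf>%.2g)=%d  pct_sig=%.1f  pct_sig_r2_all=%.1f  pct_sig_r2_of_sig=%.1f",
                        maf_thr, ld[[gs]]$n_snps, all_row$pct_sig,
                        all_row$pct_sig_r2_all, all_row$pct_sig_r2_of_sig),
                if (dd$censored == "none")
                  sprintf("decay_distance_bp=%.0f", dd$decay_distance_bp)
                else sprintf("decay_distance censored %s", dd$censored))
  }
  report <- c(report, "",
              sprintf("parameters: kb10_threshold_bp=%s slide_window_size=%s maf=%s alpha=%s r2_cut=%s min_informative=%s seed=%s",
                      kb10_thr, slide_k, maf_thr, alpha, r2_cut, min_inf,
                      config$seed %||% "NA"))
  writeLines(report, file.path(out_dir, "run_report.txt"))
  invisible(list(genotypes = geno, marker_sets = msets, haplotypes = haps,
                 diversity = div, tree = tree, ld = ld,
                 report = file.path(out_dir, "run_report.txt")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
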