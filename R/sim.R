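#' Simulation configuration for the founder-copying genotype simulator
#'
#' Describes a two-or-more subpopulation panel of inbred lines genotyped at
#' biallelic SNPs. Each subpopulation is characterized by the size of its
#' founder haplotype pool (more founders = more diversity) and by a
#' recombination intensity (more recombination = faster LD decay). The
#' defaults emulate the contrast between a large, diverse, rapidly-recombining
#' tropical pool and a narrower temperate pool typed at 2000 SNPs on 10
#' chromosomes.
#'
#' @param n_chromosomes number of chromosomes (>= 1)
#' @param chrom_length_bp chromosome length in bp
#' @param n_snps_per_chrom SNPs per chromosome, drawn uniformly without
#'   replacement from `1:chrom_length_bp`
#' @param subpops list of subpopulation specs; each a list with `name`,
#'   `n_samples`, `n_founders`, `recomb_per_bp` (switch intensity per bp per
#'   meiosis-equivalent, must lie in `[0, 1e-3]`) and `n_generations`
#'   (meiosis-equivalents accumulated)
#' @param founder_maf_range range of the uniform distribution from which each
#'   SNP's founder B-allele frequency is drawn
#' @param missing_rate per-call missing probability
#' @param het_residual_rate per-call residual-heterozygosity probability
#' @param seed integer seed; identical config + seed reproduces identical data
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_chromosomes = 10,
                       chrom_length_bp = 2e6,
                       n_snps_per_chrom = 200,
                       subpops = list(
                         list(name = "tropical", n_samples = 300,
                              n_founders = 8, recomb_per_bp = 4e-6,
                              n_generations = 10),
                         list(name = "temperate", n_samples = 150,
                              n_founders = 4, recomb_per_bp = 1.5e-6,
                              n_generations = 10)),
                       founder_maf_range = c(0.1, 0.5),
                       missing_rate = 0.02,
                       het_residual_rate = 0.005,
                       seed = 1L) {
  cfg <- structure(list(n_chromosomes = as.integer(n_chromosomes),
                        chrom_length_bp = as.integer(chrom_length_bp),
                        n_snps_per_chrom = as.integer(n_snps_per_chrom),
                        subpops = subpops,
                        founder_maf_range = as.numeric(founder_maf_range),
                        missing_rate = missing_rate,
                        het_residual_rate = het_residual_rate,
                        seed = as.integer(seed)),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_chromosomes >= 1, cfg$chrom_length_bp >= 1,
            cfg$n_snps_per_chrom >= 1,
            length(cfg$subpops) >= 1)
  for (p in c("missing_rate", "het_residual_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  if (cfg$founder_maf_range[1] < 0 || cfg$founder_maf_range[2] > 1 ||
      diff(cfg$founder_maf_range) < 0)
    stop("founder_maf_range must be an increasing interval within [0, 1]")
  for (sp in cfg$subpops) {
    need <- c("name", "n_samples", "n_founders", "recomb_per_bp",
              "n_generations")
    if (!all(need %in% names(sp)))
      stop("subpop spec needs fields: ", paste(need, collapse = ", "))
    stopifnot(sp$n_samples >= 1, sp$n_founders >= 1, sp$n_generations >= 1)
    if (sp$recomb_per_bp < 0 || sp$recomb_per_bp > 1e-3)
      stop("recomb_per_bp must lie in [0, 1e-3] (subpop ", sp$name, ")")
  }
  if (anyDuplicated(vapply(cfg$subpops, `[[`, "", "name")))
    stop("subpopulation names must be unique")
  invisible(cfg)
}

#' Simulate inbred-line genotypes from founder pools
#'
#' For each subpopulation and chromosome, `n_founders` founder haplotypes are
#' drawn (allele B at each SNP with that SNP's founder frequency). Each
#' sample's single gamete starts on a uniformly chosen founder and, walking
#' left to right, switches to a uniformly chosen founder after each inter-SNP
#' gap with probability `1 - exp(-recomb_per_bp * gap * n_generations)`.
#' The gamete is doubled into a homozygous genotype; each call then
#' independently becomes heterozygous with `het_residual_rate` and missing
#' with `missing_rate`.
#'
#' @param config a [sim_config()]
#' @return a [genotype_matrix()] with samples labelled by subpopulation
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  if (config$n_snps_per_chrom > config$chrom_length_bp)
    stop("infeasible positions: n_snps_per_chrom (", config$n_snps_per_chrom,
         ") exceeds chrom_length_bp (", config$chrom_length_bp, ")")
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  m <- config$n_snps_per_chrom

  pos_list <- lapply(chroms, function(ch)
    sort(sample.int(config$chrom_length_bp, m)))
  freq_list <- lapply(chroms, function(ch)
    stats::runif(m, config$founder_maf_range[1], config$founder_maf_range[2]))

  blocks <- vector("list", length(config$subpops))
  sample_ids <- character(0)
  sets <- character(0)
  for (s in seq_along(config$subpops)) {
    sp <- config$subpops[[s]]
    n <- sp$n_samples
    ids <- sprintf("%s_%03d", sp$name, seq_len(n))
    sample_ids <- c(sample_ids, ids)
    sets <- c(sets, rep(sp$name, n))
    chrom_mats <- vector("list", length(chroms))
    for (c in seq_along(chroms)) {
      pos <- pos_list[[c]]
      fr <- freq_list[[c]]
      founders <- matrix(stats::rbinom(sp$n_founders * m, 1L,
                                       rep(fr, each = sp$n_founders)),
                         nrow = sp$n_founders, ncol = m)
      p_switch <- 1 - exp(-sp$recomb_per_bp * diff(pos) * sp$n_generations)
      f <- sample.int(sp$n_founders, n, replace = TRUE)
      G <- matrix(0L, n, m)
      G[, 1] <- founders[cbind(f, 1L)]
      for (j in seq_len(m - 1L)) {
        sw <- stats::runif(n) < p_switch[j]
        if (any(sw)) f[sw] <- sample.int(sp$n_founders, sum(sw), replace = TRUE)
        G[, j + 1L] <- founders[cbind(f, j + 1L)]
      }
      chrom_mats[[c]] <- G
    }
    blocks[[s]] <- do.call(cbind, chrom_mats)
  }
  calls <- 2L * do.call(rbind, blocks)  # doubled gamete: hom A / hom B

  if (config$het_residual_rate > 0) {
    het <- stats::runif(length(calls)) < config$het_residual_rate
    calls[het] <- CALL_HET
  }
  if (config$missing_rate > 0) {
    mis <- stats::runif(length(calls)) < config$missing_rate
    calls[mis] <- NA_integer_
  }

  snps <- data.frame(
    snp_id = unlist(lapply(seq_along(chroms), function(c)
      sprintf("snp_%s_%04d", chroms[c], seq_len(m)))),
    chromosome = rep(chroms, each = m),
    position = unlist(pos_list),
    region_class = "unknown",
    gene_id = NA_character_,
    stringsAsFactors = FALSE)
  rownames(calls) <- sample_ids
  colnames(calls) <- snps$snp_id
  genotype_matrix(calls, snps, stats::setNames(sets, sample_ids))
}

#' Ground-truth simulation parameters per subpopulation
#'
#' Emits the per-subpopulation generating parameters (founder-pool size,
#' recombination intensity) as a table, for use by parameter-recovery tests
#' and run reports.
#'
#' @param config a [sim_config()]
#' @return data.frame with one row per subpopulation
#' @export
sim_truth <- function(config) {
  validate_sim_config(config)
  do.call(rbind, lapply(config$subpops, function(sp)
    data.frame(subpop = sp$name, n_samples = sp$n_samples,
               n_founders = sp$n_founders, recomb_per_bp = sp$recomb_per_bp,
               n_generations = sp$n_generations, stringsAsFactors = FALSE)))
}

#' Write / read the ground-truth table
#' @param config a [sim_config()]
#' @param path TSV output path
#' @return the truth table, invisibly (for `write_truth`)
#' @export
write_truth <- function(config, path) {
  tr <- sim_truth(config)
  utils::write.table(tr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tr)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
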