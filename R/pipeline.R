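# End-to-end orchestration: simulate -> homology -> effects ->
# breakpoints -> express, with one master seed fanned out to fixed
# per-stage child seeds, plain-text intermediates, and a deterministic
# machine-readable report.

#' Pipeline configuration
#'
#' @param outdir output directory for all stage files and the report.
#' @param sim a [sim_config()] controlling the synthetic inputs.
#' @param stages character vector of stages to run, from
#'   `c("simulate", "homology", "effects", "breakpoints", "express")`.
#' @param unblocked_threshold,gap_penalty,min_pair_similarity homology
#'   thresholds (0.5 / 0.2 / 0.3).
#' @param identity_min,coverage_min completeness thresholds (0.90 / 0.85).
#' @param window_size,r_threshold,b_threshold breakpoint parameters
#'   (15 / 2 / 0.25).
#' @param alpha interaction-test significance threshold (0.001).
#' @param pattern_threshold discretisation threshold for pattern labels.
#' @param blocks_bed precomputed haplotype-block BED, used by the express
#'   stage when the breakpoints stage is disabled.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            sim = sim_config(),
                            stages = c("simulate", "homology", "effects",
                                       "breakpoints", "express"),
                            unblocked_threshold = 0.5,
                            gap_penalty = 0.2,
                            min_pair_similarity = 0.3,
                            identity_min = 0.90,
                            coverage_min = 0.85,
                            window_size = 15L,
                            r_threshold = 2,
                            b_threshold = 0.25,
                            alpha = 0.001,
                            pattern_threshold = 1.0,
                            blocks_bed = NULL) {
  known <- c("simulate", "homology", "effects", "breakpoints", "express")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  stopifnot(unblocked_threshold >= 0, unblocked_threshold <= 1,
            gap_penalty >= 0, identity_min >= 0, identity_min <= 1,
            coverage_min >= 0, coverage_min <= 1, window_size >= 1,
            r_threshold > b_threshold, alpha > 0, alpha < 1)
  structure(list(outdir = outdir, sim = sim, stages = stages,
                 unblocked_threshold = unblocked_threshold,
                 gap_penalty = gap_penalty,
                 min_pair_similarity = min_pair_similarity,
                 identity_min = identity_min, coverage_min = coverage_min,
                 window_size = as.integer(window_size),
                 r_threshold = r_threshold, b_threshold = b_threshold,
                 alpha = alpha, pattern_threshold = pattern_threshold,
                 blocks_bed = blocks_bed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the [pipeline_config()] arguments,
#'   with simulation settings nested under `sim`.
#' @param outdir overrides the file's `outdir` when given.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, outdir = NULL) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  sim <- do.call(sim_config, sim_args)
  y$sim <- NULL
  if (!is.null(outdir)) y$outdir <- outdir
  do.call(pipeline_config, c(list(sim = sim), y))
}

log_msg <- function(...) message("[syntril] ", sprintf(...))

#' Run the full pipeline
#'
#' Executes the enabled stages in order, writing every intermediate as a
#' plain-text standard format under `config$outdir` and a JSON summary
#' report whose numbers are all recomputable from the stage outputs.
#' Two runs with the same configuration produce byte-identical reports.
#'
#' @param config a [pipeline_config()].
#' @return the report, invisibly (a nested list; also written to
#'   `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$sim$seed,
                 parameters = config[setdiff(names(config),
                                             c("outdir", "sim", "stages",
                                               "blocks_bed"))])
  sim_dir <- file.path(config$outdir, "simulate")

  sim <- NULL; ril <- NULL; expr <- NULL
  if ("simulate" %in% config$stages) {
    log_msg("stage simulate: seed %d", config$sim$seed)
    sim <- simulate_genome_pair(config$sim)
    write_genome_pair(sim, sim_dir)
    ril <- simulate_ril_genotypes(config$sim, parent_b_variants = sim$variants,
                                  chrom_lengths = stats::setNames(
                                    Biostrings::width(sim$genome_a$seq),
                                    names(sim$genome_a$seq)))
    write_ril_vcf(ril, file.path(sim_dir, "ril.vcf"))
    bg_truth <- ril_background_truth(sim$genome_a$genes$genes, ril)
    expr <- simulate_expression(config$sim, bg_truth)
    write_expression(expr, sim_dir)
    report$simulate <- list(
      n_genes_a = length(sim$genome_a$genes),
      n_genes_b = length(sim$genome_b$genes),
      n_blocks = nrow(sim$blocks),
      n_variants = nrow(sim$variants),
      n_true_breakpoints = nrow(ril$truth$breakpoints),
      n_true_de = nrow(expr$truth$de_genes))
  }

  if ("homology" %in% config$stages) {
    if (is.null(sim)) stop("homology stage needs the simulate stage outputs")
    log_msg("stage homology: %d + %d genes, %d blocks",
            length(sim$genome_a$genes), length(sim$genome_b$genes),
            nrow(sim$blocks))
    log_msg("  thresholds: unblocked %.2f, gap %.2f, min pair %.2f",
            config$unblocked_threshold, config$gap_penalty,
            config$min_pair_similarity)
    hom <- assign_homologs(sim$genome_a$genes, sim$genome_b$genes,
                           sim$blocks, sv_intervals = sim$sv_intervals,
                           gap_penalty = config$gap_penalty,
                           min_pair_similarity = config$min_pair_similarity,
                           unblocked_threshold = config$unblocked_threshold)
    write_homology_result(hom, file.path(config$outdir, "homology"))
    cand <- stats::setNames(hom$pairs$qry_id, hom$pairs$ref_id)
    comp <- completeness_check(sim$genome_a$genes, sim$genome_b$genes,
                               candidates = cand,
                               identity_min = config$identity_min,
                               coverage_min = config$coverage_min)
    log_msg("  completeness: %.1f%% mapped at identity >= %.2f, coverage >= %.2f",
            100 * comp$fraction, config$identity_min, config$coverage_min)
    truth_pairs <- sim$truth$homolog_map
    recovered <- sum(paste(hom$pairs$ref_id, hom$pairs$qry_id) %in%
                       paste(truth_pairs$a_gene_id, truth_pairs$b_gene_id))
    report$homology <- c(as.list(summary(hom)),
                         list(mapped_fraction = comp$fraction,
                              truth_pairs = nrow(truth_pairs),
                              truth_pairs_recovered = recovered))
  }

  if ("effects" %in% config$stages) {
    if (is.null(sim)) stop("effects stage needs the simulate stage outputs")
    log_msg("stage effects: %d variants", nrow(sim$variants))
    eff <- annotate_variants(sim$variants, sim$genome_a$genes,
                             sim$genome_a$seq)
    utils::write.table(eff, file.path(config$outdir, "effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summ <- gene_effect_summary(eff)
    utils::write.table(summ$per_gene,
                       file.path(config$outdir, "effects_per_gene.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dens <- snp_density_windows(eff,
                                stats::setNames(Biostrings::width(sim$genome_a$seq),
                                                names(sim$genome_a$seq)))
    utils::write.table(dens, file.path(config$outdir, "snp_density.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    eff_counts <- as.list(table(eff$effect))
    report$effects <- list(n_annotated = nrow(eff),
                           effect_counts = eff_counts,
                           overall_missense_silent = summ$overall_ratio,
                           n_genes_ratio_gt1 = length(summ$genes_ratio_gt1))
  }

  if ("breakpoints" %in% config$stages) {
    if (is.null(ril)) stop("breakpoints stage needs the simulate stage outputs")
    log_msg("stage breakpoints: window %d sites, R > %.2f, B < %.2f",
            config$window_size, config$r_threshold, config$b_threshold)
    sites <- filter_informative_sites(ril$variants)
    windows <- window_haplotype_calls(sites, config$window_size,
                                      config$r_threshold, config$b_threshold)
    utils::write.table(windows, file.path(config$outdir, "windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    calls <- call_breakpoints(windows)
    utils::write.table(calls$breakpoints,
                       file.path(config$outdir, "breakpoints.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_blocks_bed(calls$blocks, file.path(config$outdir, "blocks.bed"))
    per_chrom <- table(factor(calls$breakpoints$chrom,
                              levels = sort(unique(windows$chrom))))
    report$breakpoints <- list(
      n_informative_sites = nrow(sites),
      n_windows = nrow(windows),
      window_calls = as.list(table(windows$call)),
      n_breakpoints = nrow(calls$breakpoints),
      breakpoints_per_chromosome = as.list(per_chrom))
    blocks_for_express <- calls$blocks
  } else if (!is.null(config$blocks_bed)) {
    bed <- utils::read.delim(config$blocks_bed, header = FALSE,
                             col.names = c("chrom", "start", "end", "call"))
    bed$start <- bed$start + 1L  # BED is 0-based half-open
    blocks_for_express <- bed
  } else {
    blocks_for_express <- NULL
  }

  if ("express" %in% config$stages) {
    if (is.null(expr) || is.null(sim)) {
      stop("express stage needs the simulate stage outputs")
    }
    if (is.null(blocks_for_express)) {
      stop("express stage needs haplotype blocks (run breakpoints or supply blocks_bed)")
    }
    log_msg("stage express: alpha %.4g, pattern threshold %.2f",
            config$alpha, config$pattern_threshold)
    background <- assign_background(sim$genome_a$genes$genes,
                                    blocks_for_express)
    degs <- list()
    for (ts in unique(expr$samples$tissue)) {
      it <- interaction_test(expr$counts, expr$samples, ts,
                             alpha = config$alpha)
      it$background <- unname(background[it$gene_id])
      degs[[ts]] <- it
    }
    degs <- do.call(rbind, degs)
    rownames(degs) <- NULL
    utils::write.table(degs, file.path(config$outdir, "deg_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    btx_fraction <- mean(background == "BTX")
    rep_tbl <- background_filter_report(degs,
                                        background_fraction = btx_fraction)
    utils::write.table(rep_tbl, file.path(config$outdir, "deg_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    vst <- size_factors_and_vst(expr$counts)$vst
    pat <- pattern_groups(vst, expr$samples, unique(expr$samples$tissue)[1],
                          threshold = config$pattern_threshold)
    utils::write.table(pat, file.path(config$outdir, "patterns.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    per_tissue <- lapply(seq_len(nrow(rep_tbl)), function(i)
      as.list(rep_tbl[i, ]))
    names(per_tissue) <- rep_tbl$tissue
    report$express <- list(
      genome_btx_fraction = btx_fraction,
      per_tissue = per_tissue,
      n_significant = sum(degs$significant))
  }

  report_path <- file.path(config$outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log_msg("report written to %s", report_path)
  invisible(report)
}
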