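# Negative-binomial expression simulator.
#
# Counts follow NB(mu, size = 1/dispersion) with per-gene base means,
# shared stage and tissue effects (null for the interaction), and
# genotype x stage log2 fold-change patterns planted in a `de_fraction`
# of genes.  DE genes are sampled independently of their parental
# background, so the retained fraction after background filtering
# matches the background fraction in expectation.

STAGE_LABELS <- c("VEG", "RI", "FL", "ANT", "SD")
TISSUE_LABELS <- c("internode", "leaf", "meristem")

# genotype-specific per-stage log2 offsets for one DE pattern;
# stage indices follow the ordered stage labels
de_pattern_offsets <- function(pattern, n_stages, lfc) {
  z <- rep(0, n_stages)
  fl <- min(3L, n_stages - 1L)   # "flag leaf"-like stage
  ant <- min(fl + 1L, n_stages)  # the following ("anthesis"-like) stage
  switch(pattern,
    peakFL_ril_peakANT_ref = {        # RIL peaks one stage before reference
      ref <- z; ref[ant] <- lfc
      ril <- z; ril[fl] <- lfc
      list(ref = ref, ril = ril)
    },
    peakANT_ril_peakFL_ref = {
      ref <- z; ref[fl] <- lfc
      ril <- z; ril[ant] <- lfc
      list(ref = ref, ril = ril)
    },
    up_late_ref = {
      ref <- z; ref[ant:n_stages] <- lfc
      list(ref = ref, ril = z)
    },
    up_late_ril = {
      ril <- z; ril[ant:n_stages] <- lfc
      list(ref = z, ril = ril)
    },
    stop("unknown DE pattern: ", pattern))
}

#' Simulate an expression count matrix with planted interactions
#'
#' @param config a [sim_config()]; uses the design fields, `de_fraction`,
#'   `de_effect_log2fc`, `nb_dispersion`, and the seed.
#' @param background named character vector of parental backgrounds
#'   ("R"/"B") whose names are the gene ids to simulate.
#' @param genotypes character(2): reference genotype then RIL genotype
#'   (defaults `c("Rio", "PR22")`).
#' @return list of class `expression_sim`: `counts` (genes x samples
#'   integer matrix), `samples` (sample sheet with `sample`, `genotype`,
#'   `tissue`, `stage`, `replicate`), and `truth` (`de_genes` data.frame
#'   with `gene_id`, `tissue`, `pattern`; `background` copy).
#' @export
simulate_expression <- function(config, background,
                                genotypes = c("Rio", "PR22")) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_replicates < 2) {
    stop("design with < 2 replicates per cell: interaction test undefined")
  }
  if (is.null(names(background)) || !length(background)) {
    stop("'background' must be a named vector covering all genes")
  }
  with_seed(derive_seed(config$seed, "expression"), {
    genes <- names(background)
    n <- length(genes)
    stages <- if (config$n_stages <= length(STAGE_LABELS)) {
      STAGE_LABELS[seq_len(config$n_stages)]
    } else paste0("S", seq_len(config$n_stages))
    tissues <- if (config$n_tissues <= length(TISSUE_LABELS)) {
      TISSUE_LABELS[seq_len(config$n_tissues)]
    } else paste0("T", seq_len(config$n_tissues))
    gts <- genotypes[seq_len(min(2L, config$n_genotypes))]

    samples <- expand.grid(replicate = seq_len(config$n_replicates),
                           stage = stages, tissue = tissues, genotype = gts,
                           stringsAsFactors = FALSE)
    samples$sample <- sprintf("%s_%s_%s_r%d", samples$genotype,
                              samples$tissue, samples$stage,
                              samples$replicate)
    samples <- samples[, c("sample", "genotype", "tissue", "stage",
                           "replicate")]

    base_mean <- exp(stats::rnorm(n, log(250), 1))
    stage_eff <- matrix(stats::rnorm(n * length(stages), 0, 0.2), n,
                        dimnames = list(genes, stages))
    tissue_eff <- matrix(stats::rnorm(n * length(tissues), 0, 0.3), n,
                         dimnames = list(genes, tissues))

    m_de <- round(config$de_fraction * n)
    de_genes <- if (m_de > 0) sample(genes, m_de) else character(0)
    pattern_pool <- c("peakFL_ril_peakANT_ref", "peakANT_ril_peakFL_ref",
                      "up_late_ref", "up_late_ril")
    de_truth <- if (m_de > 0) {
      data.frame(gene_id = de_genes,
                 tissue = sample(tissues, m_de, replace = TRUE),
                 pattern = sample(pattern_pool, m_de, replace = TRUE),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = character(0), tissue = character(0),
                 pattern = character(0), stringsAsFactors = FALSE)
    }

    counts <- matrix(0L, n, nrow(samples),
                     dimnames = list(genes, samples$sample))
    size <- 1 / config$nb_dispersion
    de_lookup <- stats::setNames(seq_len(nrow(de_truth)), de_truth$gene_id)
    for (j in seq_len(nrow(samples))) {
      st_idx <- match(samples$stage[j], stages)
      lfc <- rep(0, n)
      if (nrow(de_truth)) {
        for (k in seq_len(nrow(de_truth))) {
          if (de_truth$tissue[k] != samples$tissue[j]) next
          off <- de_pattern_offsets(de_truth$pattern[k], length(stages),
                                    config$de_effect_log2fc)
          gi <- match(de_truth$gene_id[k], genes)
          lfc[gi] <- if (samples$genotype[j] == gts[1]) off$ref[st_idx]
                     else off$ril[st_idx]
        }
      }
      mu <- base_mean * 2^(stage_eff[, samples$stage[j]] +
                             tissue_eff[, samples$tissue[j]] + lfc)
      counts[, j] <- as.integer(stats::rnbinom(n, mu = mu, size = size))
    }
    structure(list(counts = counts, samples = samples,
                   truth = list(de_genes = de_truth,
                                background = background)),
              class = "expression_sim")
  })
}

#' Write simulated expression data as TSV
#'
#' @param expr an `expression_sim`.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_expression <- function(expr, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth_de = file.path(dir, "truth_de_genes.tsv"))
  counts_df <- data.frame(gene_id = rownames(expr$counts), expr$counts,
                          check.names = FALSE)
  utils::write.table(counts_df, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(expr$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(expr$truth$de_genes, paths["truth_de"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a count matrix and sample sheet written by [write_expression()]
#'
#' @param counts_path,samples_path paths to the TSV files.
#' @return list with `counts` (integer matrix) and `samples`.
#' @export
read_expression <- function(counts_path, samples_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene_id
  storage.mode(counts) <- "integer"
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  samples$stage <- as.character(samples$stage)
  list(counts = counts, samples = samples)
}

#' @export
print.expression_sim <- function(x, ...) {
  cat("expression_sim\n")
  cat(sprintf("  %d genes x %d samples; %d DE genes\n", nrow(x$counts),
              ncol(x$counts), nrow(x$truth$de_genes)))
  invisible(x)
}
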