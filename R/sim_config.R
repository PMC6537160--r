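#' Simulation configuration
#'
#' Builds and validates the configuration object shared by all synthetic-data
#' generators.  The defaults describe the study conditions the package
#' emulates: a pair of largely collinear genomes separated mostly by SNPs and
#' small indels (rates per bp taken from the genome-wide variant load of the
#' sweet-vs-grain sorghum comparison), single-gene tandem duplications and
#' deletions, an inbred RIL that is a homozygous mosaic of the two parental
#' haplotypes, and a 2 genotype x 3 tissue x 5 stage x 3 replicate expression
#' design with negative-binomial counts.
#'
#' @param seed integer; master seed, all outputs are pure functions of it.
#' @param n_chromosomes number of chromosomes to simulate.
#' @param genes_per_chromosome genes placed on each chromosome.
#' @param snp_rate per-bp probability of a SNP between the two genomes.
#' @param indel_rate per-bp probability of a small (1-6 bp) indel.
#' @param tandem_dup_rate per-gene probability of a single-gene tandem
#'   duplication in genome B.
#' @param deletion_rate per-gene probability of a single-gene deletion in
#'   genome B.
#' @param target_ns_s_ratio target genome-wide missense:silent ratio for
#'   planted coding SNPs (default 1.1, the observed genome-wide value).
#' @param n_breakpoints total number of recombination breakpoints in the
#'   simulated RIL genome.
#' @param genotype_error_rate per-site probability that the RIL genotype is
#'   flipped to the other parental homozygote.
#' @param missing_rate per-sample, per-site probability of a missing call.
#' @param n_genotypes,n_tissues,n_stages,n_replicates expression design.
#' @param de_fraction fraction of genes given a genotype-by-time interaction.
#' @param de_effect_log2fc log2 fold change of the planted interaction.
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param gene_codons_range range of CDS lengths in codons (including the
#'   start and stop codons).
#' @param spacer_range range of intergenic spacer lengths in bp.
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_chromosomes = 1, genes_per_chromosome = 10)
#' cfg$snp_rate
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       genes_per_chromosome = 60L,
                       snp_rate = 2.6e-3,
                       indel_rate = 5.4e-4,
                       tandem_dup_rate = 0.015,
                       deletion_rate = 0.03,
                       target_ns_s_ratio = 1.1,
                       n_breakpoints = 6L,
                       genotype_error_rate = 0.002,
                       missing_rate = 0.01,
                       n_genotypes = 2L,
                       n_tissues = 3L,
                       n_stages = 5L,
                       n_replicates = 3L,
                       de_fraction = 0.08,
                       de_effect_log2fc = 2,
                       nb_dispersion = 0.05,
                       gene_codons_range = c(60L, 150L),
                       spacer_range = c(800L, 2000L)) {
  cfg <- list(
    seed = seed,
    n_chromosomes = n_chromosomes,
    genes_per_chromosome = genes_per_chromosome,
    snp_rate = snp_rate,
    indel_rate = indel_rate,
    tandem_dup_rate = tandem_dup_rate,
    deletion_rate = deletion_rate,
    target_ns_s_ratio = target_ns_s_ratio,
    n_breakpoints = n_breakpoints,
    genotype_error_rate = genotype_error_rate,
    missing_rate = missing_rate,
    n_genotypes = n_genotypes,
    n_tissues = n_tissues,
    n_stages = n_stages,
    n_replicates = n_replicates,
    de_fraction = de_fraction,
    de_effect_log2fc = de_effect_log2fc,
    nb_dispersion = nb_dispersion,
    gene_codons_range = gene_codons_range,
    spacer_range = spacer_range
  )
  validate_sim_config(cfg)  # validates before integer coercion
  for (p in c("seed", "n_chromosomes", "genes_per_chromosome",
              "n_breakpoints", "n_genotypes", "n_tissues", "n_stages",
              "n_replicates", "gene_codons_range", "spacer_range")) {
    cfg[[p]] <- as.integer(cfg[[p]])
  }
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c("snp_rate", "indel_rate", "tandem_dup_rate", "deletion_rate",
             "genotype_error_rate", "missing_rate", "de_fraction")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("'%s' must be a probability in [0, 1], got %s", p,
                   format(v)), call. = FALSE)
    }
  }
  counts <- c("n_chromosomes", "genes_per_chromosome", "n_breakpoints",
              "n_genotypes", "n_tissues", "n_stages", "n_replicates")
  for (p in counts) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 ||
        v != round(v)) {
      stop(sprintf("'%s' must be a non-negative count, got %s", p,
                   format(v)), call. = FALSE)
    }
  }
  if (cfg$n_chromosomes < 1 || cfg$genes_per_chromosome < 1) {
    stop("need at least one chromosome and one gene per chromosome",
         call. = FALSE)
  }
  if (cfg$target_ns_s_ratio <= 0) {
    stop("'target_ns_s_ratio' must be positive", call. = FALSE)
  }
  if (cfg$nb_dispersion <= 0) stop("'nb_dispersion' must be positive",
                                   call. = FALSE)
  if (cfg$gene_codons_range[1] < 10 ||
      cfg$gene_codons_range[2] < cfg$gene_codons_range[1]) {
    stop("invalid 'gene_codons_range'", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-data configuration (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  genomes : %d chromosome(s) x %d genes, snp %.2g/bp, indel %.2g/bp\n",
              x$n_chromosomes, x$genes_per_chromosome, x$snp_rate, x$indel_rate))
  cat(sprintf("  events  : tandem dup %.3g/gene, deletion %.3g/gene, NS:S target %.2f\n",
              x$tandem_dup_rate, x$deletion_rate, x$target_ns_s_ratio))
  cat(sprintf("  RIL     : %d breakpoints, error %.3g, missing %.3g\n",
              x$n_breakpoints, x$genotype_error_rate, x$missing_rate))
  cat(sprintf("  design  : %d genotypes x %d tissues x %d stages x %d reps, DE %.2g @ log2FC %.1f, disp %.2g\n",
              x$n_genotypes, x$n_tissues, x$n_stages, x$n_replicates,
              x$de_fraction, x$de_effect_log2fc, x$nb_dispersion))
  invisible(x)
}
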