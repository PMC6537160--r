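# Simplified variant-effect annotation.
#
# Each SNP or small indel is classified against the canonical transcript
# of the gene containing it: codon-aware (strand-aware) translation of the
# affected codon for CDS SNPs, frame arithmetic for CDS indels, positional
# classes (intron / UTR / upstream / downstream / intergenic) elsewhere.
# Impact follows the fixed effect -> impact map used by common annotators.

EFFECT_IMPACT <- c(
  synonymous = "LOW",
  missense = "MODERATE",
  stop_gained = "HIGH",
  stop_lost = "HIGH",
  start_lost = "HIGH",
  frameshift = "HIGH",
  inframe_insertion = "MODERATE",
  inframe_deletion = "MODERATE",
  intron = "MODIFIER",
  utr = "MODIFIER",
  upstream = "MODIFIER",
  downstream = "MODIFIER",
  intergenic = "MODIFIER")

# Per-gene lookup tables reused across variants.
build_gene_index <- function(gs) {
  g <- gs$genes
  idx <- list()
  for (ch in unique(g$chrom)) {
    rows <- which(g$chrom == ch)
    idx[[ch]] <- rows[order(g$start[rows])]
  }
  cds_pos <- lapply(seq_len(nrow(g)), function(i) {
    cds_positions(gs$cds[[g$gene_id[i]]], g$strand[i])
  })
  list(genes = g, by_chrom = idx, cds_pos = cds_pos, exons = gs$exons,
       cds = gs$cds)
}

#' Annotate variants with effect and impact classes
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`; multi-allelic records must already be split (see
#'   [read_vcf_variants()]).
#' @param gs a [gene_set] (only the canonical transcript of each gene is
#'   annotated).
#' @param genome [Biostrings::DNAStringSet] named by chromosome; used to
#'   verify the ref allele and to build codons.
#' @param flank upstream/downstream window in bp (default 5000).
#' @return data.frame: the input columns plus `kind`, `gene_id`, `effect`,
#'   `impact`, `protein_change`.
#' @examples
#' sim <- simulate_genome_pair(sim_config(seed = 3, n_chromosomes = 1,
#'                                        genes_per_chromosome = 5))
#' eff <- annotate_variants(head(sim$variants), sim$genome_a$genes,
#'                          sim$genome_a$seq)
#' table(eff$effect)
#' @export
annotate_variants <- function(variants, gs, genome, flank = 5000L) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  idx <- build_gene_index(gs)
  chars <- lapply(as.character(genome), function(s)
    strsplit(s, "", fixed = TRUE)[[1]])
  n <- nrow(variants)
  effect <- character(n); gene_id <- rep(NA_character_, n)
  prot <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    v <- variants[i, ]
    ch <- chars[[v$chrom]]
    if (is.null(ch)) stop("variant chromosome not in genome: ", v$chrom)
    ref_here <- paste(ch[v$pos:(v$pos + nchar(v$ref) - 1L)], collapse = "")
    if (!identical(ref_here, toupper(v$ref))) {
      stop(sprintf("ref allele mismatch at %s:%d (VCF %s, genome %s)",
                   v$chrom, v$pos, v$ref, ref_here))
    }
    ann <- annotate_one(v, idx, ch, flank)
    effect[i] <- ann$effect
    gene_id[i] <- ann$gene_id
    prot[i] <- ann$protein_change
  }
  out <- variants
  out$kind <- variant_kind(out$ref, out$alt)
  out$gene_id <- gene_id
  out$effect <- effect
  out$impact <- unname(EFFECT_IMPACT[effect])
  out$protein_change <- prot
  out
}

annotate_one <- function(v, idx, ch, flank) {
  g <- idx$genes
  rows <- idx$by_chrom[[v$chrom]]
  none <- list(effect = "intergenic", gene_id = NA_character_,
               protein_change = NA_character_)
  if (is.null(rows)) return(none)
  is_snp <- nchar(v$ref) == 1L && nchar(v$alt) == 1L
  indel_len <- abs(nchar(v$ref) - nchar(v$alt))
  is_ins <- nchar(v$alt) > nchar(v$ref)

  hit <- rows[g$start[rows] <= v$pos & g$end[rows] >= v$pos]
  if (length(hit)) {
    gi <- hit[1]  # first (canonical) gene when models overlap
    gid <- g$gene_id[gi]
    strand <- g$strand[gi]
    cds_pos <- idx$cds_pos[[gi]]
    cds_df <- idx$cds[[gid]]
    if (is_snp) {
      if (v$pos %in% cds_pos) {
        return(c(classify_cds_snp(v, cds_pos, strand, ch), gene_id = gid))
      }
      ex <- idx$exons[[gid]]
      in_exon <- any(v$pos >= ex$start & v$pos <= ex$end)
      return(list(effect = if (in_exon) "utr" else "intron", gene_id = gid,
                  protein_change = NA_character_))
    }
    # indel: inserted bases fall between pos and pos+1; deleted bases span
    # pos+1 .. pos+len (VCF anchored representation)
    touches_cds <- if (is_ins) {
      any(v$pos >= cds_df$start & v$pos < cds_df$end)
    } else {
      d1 <- v$pos + 1L; d2 <- v$pos + indel_len
      any(pmax(cds_df$start, d1) <= pmin(cds_df$end, d2))
    }
    if (touches_cds) {
      eff <- if (indel_len %% 3L != 0L) "frameshift"
             else if (is_ins) "inframe_insertion" else "inframe_deletion"
      return(list(effect = eff, gene_id = gid,
                  protein_change = NA_character_))
    }
    ex <- idx$exons[[gid]]
    in_exon <- any(v$pos >= ex$start & v$pos <= ex$end)
    return(list(effect = if (in_exon) "utr" else "intron", gene_id = gid,
                protein_change = NA_character_))
  }

  # nearest gene within the flank
  d_up <- g$start[rows] - v$pos   # positive when variant is 5' of gene start
  d_dn <- v$pos - g$end[rows]
  near <- which((d_up > 0 & d_up <= flank) | (d_dn > 0 & d_dn <= flank))
  if (length(near)) {
    dists <- pmin(ifelse(d_up[near] > 0, d_up[near], Inf),
                  ifelse(d_dn[near] > 0, d_dn[near], Inf))
    k <- near[which.min(dists)]
    gi <- rows[k]
    before_start <- g$start[gi] > v$pos
    eff <- if (g$strand[gi] == "+") {
      if (before_start) "upstream" else "downstream"
    } else {
      if (before_start) "downstream" else "upstream"
    }
    return(list(effect = eff, gene_id = g$gene_id[gi],
                protein_change = NA_character_))
  }
  none
}

classify_cds_snp <- function(v, cds_pos, strand, ch) {
  i <- match(v$pos, cds_pos)
  codon_idx <- (i - 1L) %/% 3L
  within <- (i - 1L) %% 3L
  cps <- cds_pos[codon_idx * 3L + 1:3]
  bases <- ch[cps]
  if (strand == "-") bases <- COMPLEMENT[bases]
  ref_codon <- paste(bases, collapse = "")
  mut <- bases
  mut[within + 1L] <- if (strand == "-") COMPLEMENT[[toupper(v$alt)]]
                      else toupper(v$alt)
  alt_codon <- paste(mut, collapse = "")
  aa0 <- codon_aa(ref_codon); aa1 <- codon_aa(alt_codon)
  res_no <- codon_idx + 1L
  pc <- sprintf("%s%d%s", aa0, res_no, aa1)
  if (aa0 == aa1) list(effect = "synonymous", protein_change = pc)
  else if (aa1 == "*") list(effect = "stop_gained", protein_change = pc)
  else if (aa0 == "*") list(effect = "stop_lost", protein_change = pc)
  else if (codon_idx == 0L) list(effect = "start_lost", protein_change = pc)
  else list(effect = "missense", protein_change = pc)
}

#' Per-gene and overall missense:silent summaries
#'
#' Silent counts synonymous SNPs only; missense counts missense SNPs only.
#' The overall ratio is total missense over total silent; the flagged list
#' uses a strict `ratio > 1`, and genes with missense but no silent SNPs
#' (infinite ratio) are included in it.
#'
#' @param effects annotated variant table from [annotate_variants()].
#' @return list with `per_gene` (data.frame `gene_id`, `missense_count`,
#'   `silent_count`, `ratio`), `overall_ratio`, and `genes_ratio_gt1`
#'   (character vector).
#' @export
gene_effect_summary <- function(effects) {
  coding <- effects[effects$effect %in% c("missense", "synonymous") &
                      !is.na(effects$gene_id), , drop = FALSE]
  gids <- sort(unique(coding$gene_id))
  mis <- vapply(gids, function(g)
    sum(coding$gene_id == g & coding$effect == "missense"), integer(1))
  sil <- vapply(gids, function(g)
    sum(coding$gene_id == g & coding$effect == "synonymous"), integer(1))
  ratio <- ifelse(sil > 0, mis / sil, ifelse(mis > 0, Inf, NA_real_))
  per_gene <- data.frame(gene_id = gids, missense_count = mis,
                         silent_count = sil, ratio = ratio,
                         stringsAsFactors = FALSE)
  rownames(per_gene) <- NULL
  total_m <- sum(mis); total_s <- sum(sil)
  list(per_gene = per_gene,
       overall_ratio = if (total_s > 0) total_m / total_s else NA_real_,
       genes_ratio_gt1 = per_gene$gene_id[!is.na(per_gene$ratio) &
                                            per_gene$ratio > 1])
}

#' Windowed SNP density
#'
#' Counts SNPs in sliding windows (default 1 Mb window, 200 kb step) and
#' reports density scaled to SNPs per 200 kb.  Trailing windows truncated
#' by the chromosome end are scaled by their actual width.
#'
#' @param variants variant table; only rows with `kind == "snp"` (or
#'   1-bp ref/alt when `kind` is absent) are counted.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param window window size in bp (default 1e6).
#' @param step step between window starts in bp (default 2e5).
#' @return data.frame with `chrom`, `start`, `end`, `n_snps`, `density`
#'   (SNPs per 200 kb).
#' @export
snp_density_windows <- function(variants, chrom_lengths, window = 1e6,
                                step = 2e5) {
  if (!"kind" %in% names(variants)) {
    variants$kind <- variant_kind(variants$ref, variants$alt)
  }
  snps <- variants[variants$kind == "snp", , drop = FALSE]
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    starts <- seq(1, len, by = step)
    ends <- pmin(starts + window - 1, len)
    pos <- snps$pos[snps$chrom == ch]
    counts <- vapply(seq_along(starts), function(k)
      sum(pos >= starts[k] & pos <= ends[k]), integer(1))
    width <- ends - starts + 1
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            n_snps = counts,
                            density = counts * (2e5 / width),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
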