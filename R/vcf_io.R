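# Plain-text VCF 4.2 emission and variant-table ingestion.
# Reading goes through vcfR; writing is a simple text emitter because the
# simulators hold variants as plain data.frames.

#' Write variants (optionally with genotypes) as VCF 4.2
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param path output path.
#' @param genotypes optional character matrix (sites x samples) of GT
#'   strings such as "0/0", "1/1", "./."; column names are sample names.
#' @param contigs optional named integer vector of contig lengths for the
#'   header.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(variants, path, genotypes = NULL, contigs = NULL) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=syntril"), con)
  if (!is.null(contigs)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                       as.integer(contigs)), con)
  }
  header <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(genotypes)) {
    writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               con)
    header <- c(header, "FORMAT", colnames(genotypes))
  }
  writeLines(paste(header, collapse = "\t"), con)
  fixed <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                   variants$chrom, as.integer(variants$pos),
                   variants$ref, variants$alt)
  if (!is.null(genotypes)) {
    gt <- apply(genotypes, 1, paste, collapse = "\t")
    fixed <- paste(fixed, "GT", gt, sep = "\t")
  }
  writeLines(fixed, con)
  invisible(path)
}

#' Read a VCF into a variant table
#'
#' Uses [vcfR::read.vcfR()]; multi-allelic records are split into biallelic
#' variants before downstream annotation.  Each variant is classified as a
#' SNP, insertion, or deletion from its allele lengths.
#'
#' @param path VCF path (plain or gzipped).
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `kind`,
#'   plus one genotype column per sample when the file carries genotypes.
#' @export
read_vcf_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- if (ncol(v@gt) > 1) {
    g <- vcfR::extract.gt(v, element = "GT")
    g[is.na(g)] <- "./."  # vcfR reads missing genotypes as NA
    g
  } else NULL
  out <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (a in alts) {
      row <- data.frame(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
                        ref = fix$REF[i], alt = a, stringsAsFactors = FALSE)
      if (!is.null(gt)) {
        for (s in colnames(gt)) row[[s]] <- gt[i, s]
      }
      out[[length(out) + 1]] <- row
    }
  }
  res <- do.call(rbind, out)
  res$kind <- variant_kind(res$ref, res$alt)
  rownames(res) <- NULL
  res
}

variant_kind <- function(ref, alt) {
  ifelse(nchar(ref) == nchar(alt) & nchar(ref) == 1, "snp",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}
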