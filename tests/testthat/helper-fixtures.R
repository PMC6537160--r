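# Small constructed fixtures shared across test files.

# A gene_set whose transcripts are supplied directly (no genome needed);
# every gene is single-exon with CDS == exon == gene span.
toy_gene_set <- function(ids, chrom, starts, ends, strands = NULL,
                         transcripts = NULL) {
  n <- length(ids)
  if (is.null(strands)) strands <- rep("+", n)
  if (is.null(transcripts)) {
    transcripts <- stats::setNames(
      vapply(ends - starts + 1, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""), character(1)), ids)
  }
  genes <- data.frame(gene_id = ids, chrom = chrom, start = starts,
                      end = ends, strand = strands, stringsAsFactors = FALSE)
  segs <- lapply(seq_len(n), function(i)
    data.frame(start = starts[i], end = ends[i]))
  names(segs) <- ids
  gene_set(genes, exons = segs, cds = segs, transcript = transcripts)
}

# One hand-built chromosome: 60 bp pad | gene | 60 bp pad, with the gene's
# CDS given explicitly so every codon position is known.
#   layout (plus strand): u5 (12 bp) | CDS | u3 (12 bp), single exon
crafted_gene_chrom <- function(cds, strand = "+", pad = 60L, u = 12L) {
  u5 <- paste(rep("C", u), collapse = "")
  u3 <- paste(rep("G", u), collapse = "")
  body <- paste0(u5, cds, u3)
  if (strand == "-") {
    body <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(body)))
  }
  chrom_seq <- paste0(paste(rep("A", pad), collapse = ""), body,
                      paste(rep("T", pad), collapse = ""))
  gene_start <- pad + 1L
  gene_end <- pad + nchar(body)
  if (strand == "+") {
    cds_start <- gene_start + u
    cds_end <- cds_start + nchar(cds) - 1L
  } else {
    cds_start <- gene_start + u  # u3 occupies the first u bases on "-"
    cds_end <- cds_start + nchar(cds) - 1L
  }
  genes <- data.frame(gene_id = "g1", chrom = "chrT", start = gene_start,
                      end = gene_end, strand = strand,
                      stringsAsFactors = FALSE)
  exons <- list(g1 = data.frame(start = gene_start, end = gene_end))
  cds_segs <- list(g1 = data.frame(start = cds_start, end = cds_end))
  genome <- Biostrings::DNAStringSet(c(chrT = chrom_seq))
  list(gs = gene_set(genes, exons, cds_segs, genome = genome),
       genome = genome, seq = chrom_seq,
       cds_range = c(cds_start, cds_end))
}

# Crafted 3-sample genotype table for the site filters.
ril_variant_row <- function(pos, rio, btx, pr22, ref = "A", alt = "G") {
  data.frame(chrom = "chr01", pos = pos, ref = ref, alt = alt,
             Rio = rio, BTx3197 = btx, PR22 = pr22,
             stringsAsFactors = FALSE)
}
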