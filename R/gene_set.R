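#' Gene-set container
#'
#' A light container for one annotated genome: a gene table, per-gene exon
#' and CDS segments (genomic, ascending), and the spliced transcript
#' sequence of the canonical (first) mRNA of each gene.  Coordinates are
#' 1-based inclusive throughout, the native convention of GFF3 and of the
#' Bioconductor ranges stack; the only conversion point is BED output.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` ("+" or "-").
#' @param exons named list (by `gene_id`) of data.frames with columns
#'   `start`, `end`, sorted ascending by start.
#' @param cds named list like `exons`, giving coding segments.
#' @param genome [Biostrings::DNAStringSet] named by chromosome, used to
#'   derive transcript sequences; alternatively pass `transcript` directly.
#' @param transcript optional named character vector of spliced transcript
#'   sequences (transcript orientation).
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(genes, exons, cds, genome = NULL, transcript = NULL) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(genes)))
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  if (any(genes$start >= genes$end)) stop("gene start must be < end")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (is.null(transcript)) {
    if (is.null(genome)) stop("supply either 'genome' or 'transcript'")
    transcript <- extract_transcripts(genes, exons, genome)
  }
  structure(list(genes = genes,
                 exons = exons[genes$gene_id],
                 cds = cds[genes$gene_id],
                 transcript = transcript[genes$gene_id]),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set: %d genes on %d chromosome(s)\n",
              nrow(x$genes), length(unique(x$genes$chrom))))
  cat(sprintf("  transcript lengths %d-%d nt\n",
              min(nchar(x$transcript)), max(nchar(x$transcript))))
  invisible(x)
}

#' @export
length.gene_set <- function(x) nrow(x$genes)

# Spliced transcript sequences (exon union, reverse-complemented for "-").
extract_transcripts <- function(genes, exons, genome) {
  out <- character(nrow(genes))
  names(out) <- genes$gene_id
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    ex <- exons[[gid]]
    chrom_seq <- genome[[genes$chrom[i]]]
    pieces <- vapply(seq_len(nrow(ex)), function(j) {
      as.character(Biostrings::subseq(chrom_seq, ex$start[j], ex$end[j]))
    }, character(1))
    tx <- paste(pieces, collapse = "")
    if (genes$strand[i] == "-") tx <- revcomp_chr(tx)
    out[gid] <- tx
  }
  out
}

#' Read an annotated genome into a gene_set
#'
#' Parses a GFF3 (gene/mRNA/exon/CDS features) with [rtracklayer::import()]
#' and a FASTA with [Biostrings::readDNAStringSet()], keeping the first mRNA
#' of each gene as its canonical transcript.
#'
#' @param gff_path path to a GFF3 file.
#' @param fasta_path path to the matching genome FASTA.
#' @return a [gene_set].
#' @export
read_gene_set <- function(gff_path, fasta_path) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  df <- as.data.frame(gr)
  parent <- vapply(df$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                   character(1))
  gene_rows <- df[df$type == "gene", , drop = FALSE]
  mrna_rows <- df[df$type == "mRNA", , drop = FALSE]
  genes <- data.frame(gene_id = gene_rows$ID,
                      chrom = as.character(gene_rows$seqnames),
                      start = gene_rows$start, end = gene_rows$end,
                      strand = as.character(gene_rows$strand),
                      stringsAsFactors = FALSE)
  # first mRNA per gene is canonical
  mrna_parent <- parent[df$type == "mRNA"]
  canonical <- mrna_rows$ID[!duplicated(mrna_parent)]
  names(canonical) <- mrna_parent[!duplicated(mrna_parent)]
  exons <- list(); cds <- list()
  for (gid in genes$gene_id) {
    tid <- canonical[[gid]]
    ex <- df[df$type == "exon" & parent == tid, c("start", "end")]
    cd <- df[df$type == "CDS" & parent == tid, c("start", "end")]
    exons[[gid]] <- ex[order(ex$start), , drop = FALSE]
    cds[[gid]] <- cd[order(cd$start), , drop = FALSE]
  }
  gene_set(genes, exons, cds, genome = genome)
}

#' Write a gene_set annotation as GFF3
#'
#' @param gs a [gene_set].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(gs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  src <- "syntril"
  for (i in seq_len(nrow(gs$genes))) {
    g <- gs$genes[i, ]
    tid <- paste0(g$gene_id, ".1")
    lines <- c(
      sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, src, g$start, g$end, g$strand, g$gene_id),
      sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chrom, src, g$start, g$end, g$strand, tid, g$gene_id)
    )
    ex <- gs$exons[[g$gene_id]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                                g$chrom, src, ex$start[j], ex$end[j],
                                g$strand, tid, j, tid))
    }
    cd <- gs$cds[[g$gene_id]]
    # phase: number of bases of the first (in translation order) segments
    # carried over into this one
    ord <- if (g$strand == "+") seq_len(nrow(cd)) else rev(seq_len(nrow(cd)))
    lens <- cd$end - cd$start + 1
    phase <- integer(nrow(cd))
    carried <- 0L
    for (j in ord) {
      phase[j] <- (3L - carried %% 3L) %% 3L
      carried <- carried + lens[j]
    }
    for (j in seq_len(nrow(cd))) {
      lines <- c(lines, sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
                                g$chrom, src, cd$start[j], cd$end[j],
                                g$strand, phase[j], tid, tid))
    }
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a genome FASTA (60-column wrapped)
#'
#' @param genome [Biostrings::DNAStringSet] named by chromosome.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}
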