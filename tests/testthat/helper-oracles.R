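# Independent oracles, deliberately implemented by routes different from
# the package code they check.

# Best total score over ALL monotone pairings of two gene lists, by
# exhaustive recursion (no dynamic-programming table): a matched pair
# contributes its similarity, every unpaired gene costs `gap`.
brute_force_alignment_score <- function(sim, gap) {
  n <- nrow(sim); m <- ncol(sim)
  rec <- function(i, j) {
    if (i > n && j > m) return(0)
    if (i > n) return(-gap * (m - j + 1))
    if (j > m) return(-gap * (n - i + 1))
    max(rec(i + 1, j) - gap,
        rec(i, j + 1) - gap,
        rec(i + 1, j + 1) + sim[i, j])
  }
  rec(1L, 1L)
}

# Classify a single-base CDS substitution by translating the FULL mutated
# coding sequence and comparing proteins (the package classifies from the
# affected codon only).  Codon-by-codon table translation, literal first
# codon (no initiator-codon rules).
oracle_translate <- function(cds) {
  starts <- seq(1L, nchar(cds), by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  unname(Biostrings::GENETIC_CODE[codons])
}

oracle_snp_effect <- function(chrom_seq, gs, gid, pos, alt) {
  g <- gs$genes[gs$genes$gene_id == gid, ]
  segs <- gs$cds[[gid]]
  mutated <- chrom_seq
  substr(mutated, pos, pos) <- alt
  extract_cds <- function(seq) {
    s <- paste(vapply(seq_len(nrow(segs)), function(j)
      substr(seq, segs$start[j], segs$end[j]), character(1)), collapse = "")
    if (g$strand == "-") {
      s <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                 collapse = "")
    }
    s
  }
  p0 <- oracle_translate(extract_cds(chrom_seq))
  p1 <- oracle_translate(extract_cds(mutated))
  if (identical(p0, p1)) return("synonymous")
  d <- which(p0 != p1)[1]
  if (p1[d] == "*") "stop_gained"
  else if (p0[d] == "*") "stop_lost"
  else if (d == 1L) "start_lost"
  else "missense"
}
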