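# Synthetic genome-pair generator.
#
# Genome A is assembled from random-codon ORF genes (ATG ... stop) separated
# by random intergenic spacers; genome B is derived from A by planting SNPs
# and small indels at configured per-bp rates, and single-gene tandem
# duplications and deletions at configured per-gene rates.  Every planted
# event is recorded in a truth ledger, and the emitted alignment-block table
# covers all collinear segments, split at structural events.

SENSE_CODONS <- NULL  # initialised lazily (needs Biostrings at run time)
STOP_CODONS <- c("TAA", "TAG", "TGA")

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# One gene laid out on the transcript-forward axis, then mirrored if "-".
# Returns genomic (+ strand) sequence and relative 1-based feature coords.
build_gene <- function(cfg) {
  n_cod <- resample(seq(cfg$gene_codons_range[1], cfg$gene_codons_range[2]),
                    1)
  codons <- c("ATG",
              sample(sense_codons(), n_cod - 2L, replace = TRUE),
              sample(STOP_CODONS, 1))
  cds_seq <- paste(codons, collapse = "")
  cds_len <- nchar(cds_seq)
  n_ex <- if (cds_len >= 70L) sample(1:3, 1) else 1L
  cuts <- integer(0)
  if (n_ex > 1) {
    for (try in 1:20) {
      cand <- sort(resample(seq(25L, cds_len - 25L), n_ex - 1L))
      if (all(diff(c(0L, cand, cds_len)) >= 20L)) { cuts <- cand; break }
    }
    if (!length(cuts)) n_ex <- 1L
  }
  piece_bounds <- cbind(start = c(1L, cuts + 1L), end = c(cuts, cds_len))
  u5 <- random_dna(sample(30:80, 1))
  u3 <- random_dna(sample(30:80, 1))
  introns <- replicate(max(0L, n_ex - 1L), random_dna(sample(60:120, 1)))

  # transcript-forward layout
  seq_parts <- character(0)
  exon <- cds <- data.frame(start = integer(0), end = integer(0))
  p <- 1L
  for (j in seq_len(n_ex)) {
    piece <- substr(cds_seq, piece_bounds[j, "start"], piece_bounds[j, "end"])
    ex_start <- p
    if (j == 1L) { seq_parts <- c(seq_parts, u5); p <- p + nchar(u5) }
    cds_start <- p
    seq_parts <- c(seq_parts, piece); p <- p + nchar(piece)
    cds <- rbind(cds, data.frame(start = cds_start, end = p - 1L))
    if (j == n_ex) { seq_parts <- c(seq_parts, u3); p <- p + nchar(u3) }
    exon <- rbind(exon, data.frame(start = ex_start, end = p - 1L))
    if (j < n_ex) { seq_parts <- c(seq_parts, introns[j]); p <- p + nchar(introns[j]) }
  }
  body <- paste(seq_parts, collapse = "")
  len <- nchar(body)
  strand <- sample(c("+", "-"), 1)
  if (strand == "-") {
    body <- revcomp_chr(body)
    mirror <- function(df) {
      out <- data.frame(start = len - df$end + 1L, end = len - df$start + 1L)
      out[order(out$start), , drop = FALSE]
    }
    exon <- mirror(exon); cds <- mirror(cds)
  }
  list(seq = body, len = len, strand = strand, exons = exon, cds = cds)
}

# CDS genomic positions in translation order (descending for "-").
cds_positions <- function(cds_df, strand) {
  pos <- unlist(Map(seq, cds_df$start, cds_df$end), use.names = FALSE)
  if (strand == "-") rev(pos) else pos
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Classify the planted SNP (pos, alt) against the gene's codon structure.
classify_coding_snp <- function(chars, cds_pos, strand, pos, alt) {
  i <- match(pos, cds_pos)
  codon_idx <- (i - 1L) %/% 3L
  within <- (i - 1L) %% 3L
  cps <- cds_pos[codon_idx * 3L + 1:3]
  bases <- chars[cps]
  if (strand == "-") bases <- COMPLEMENT[bases]
  ref_codon <- paste(bases, collapse = "")
  mut <- bases
  mut[within + 1L] <- if (strand == "-") COMPLEMENT[[alt]] else alt
  alt_codon <- paste(mut, collapse = "")
  aa0 <- codon_aa(ref_codon); aa1 <- codon_aa(alt_codon)
  if (aa0 == aa1) "synonymous"
  else if (aa1 == "*") "stop_gained"
  else if (aa0 == "*") "stop_lost"
  else if (codon_idx == 0L) "start_lost"
  else "missense"
}

#' Simulate a pair of largely collinear annotated genomes
#'
#' Genome B is derived from genome A by planting SNPs and small (1-6 bp)
#' indels at the configured per-bp rates, and single-gene tandem
#' duplications and deletions at the configured per-gene rates.  Coding
#' SNP placement is rejection-sampled within codons so the genome-wide
#' missense:silent ratio matches `target_ns_s_ratio` in expectation.
#' Overlapping small-variant proposals are re-drawn up to a hard cap,
#' after which the generator fails.
#'
#' @param config a [sim_config()].
#' @return an object of class `genome_pair_sim`: a list with elements
#'   `genome_a`, `genome_b` (each `$seq` a DNAStringSet and `$genes` a
#'   [gene_set]), `blocks` (collinear alignment-block table), `variants`
#'   (small-variant table, genome-A coordinates), `sv_intervals`
#'   (structural-event intervals on both genomes), and `truth` (ledger:
#'   `homolog_map`, `pav_genes`, `paralog_copies`, `planted_variants`).
#' @examples
#' sim <- simulate_genome_pair(sim_config(seed = 7, n_chromosomes = 1,
#'                                        genes_per_chromosome = 8))
#' nrow(sim$truth$homolog_map)
#' @export
simulate_genome_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "genome_pair"),
            simulate_genome_pair_impl(config))
}

simulate_genome_pair_impl <- function(cfg) {
  chrom_names <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))
  genomeA <- character(0); genomeB <- character(0)
  genesA_rows <- list(); exonsA <- list(); cdsA <- list()
  genesB_rows <- list(); exonsB <- list(); cdsB <- list()
  blocks <- list(); variants <- list(); sv_intervals <- list()
  homolog <- list(); pav <- list(); paralogs <- list(); planted <- list()

  # estimate acceptance probability for missense proposals once per genome
  accept_missense <- NA_real_

  for (ci in seq_along(chrom_names)) {
    chrom <- chrom_names[ci]
    ng <- cfg$genes_per_chromosome

    genes <- vector("list", ng)
    for (i in seq_len(ng)) genes[[i]] <- build_gene(cfg)

    spacers <- replicate(ng + 1L,
                         random_dna(sample(seq(cfg$spacer_range[1],
                                               cfg$spacer_range[2]), 1)))
    parts <- character(0); offs <- integer(ng)
    p <- 1L
    for (i in seq_len(ng)) {
      parts <- c(parts, spacers[i]); p <- p + nchar(spacers[i])
      offs[i] <- p
      parts <- c(parts, genes[[i]]$seq); p <- p + genes[[i]]$len
    }
    parts <- c(parts, spacers[ng + 1L])
    seqA <- paste(parts, collapse = "")
    chrom_len <- nchar(seqA)
    chars <- strsplit(seqA, "", fixed = TRUE)[[1]]

    a_ids <- sprintf("gA_%02d_%04d", ci, seq_len(ng))
    gene_abs <- lapply(seq_len(ng), function(i) {
      g <- genes[[i]]
      list(id = a_ids[i], start = offs[i], end = offs[i] + g$len - 1L,
           strand = g$strand,
           exons = data.frame(start = g$exons$start + offs[i] - 1L,
                              end = g$exons$end + offs[i] - 1L),
           cds = data.frame(start = g$cds$start + offs[i] - 1L,
                            end = g$cds$end + offs[i] - 1L))
    })

    # per-bp region classes and gene index, used for truth labels and to
    # keep indels inside a single feature
    region <- rep("intergenic", chrom_len)
    gene_of <- rep(NA_integer_, chrom_len)
    for (i in seq_len(ng)) {
      g <- gene_abs[[i]]
      region[g$start:g$end] <- "intron"
      gene_of[g$start:g$end] <- i
      for (j in seq_len(nrow(g$exons)))
        region[g$exons$start[j]:g$exons$end[j]] <- "utr"
      for (j in seq_len(nrow(g$cds)))
        region[g$cds$start[j]:g$cds$end[j]] <- "cds"
    }
    cds_pos_list <- lapply(gene_abs, function(g) cds_positions(g$cds, g$strand))

    if (is.na(accept_missense) && cfg$snp_rate > 0) {
      accept_missense <- estimate_missense_acceptance(
        chars, gene_abs, cds_pos_list, cfg$target_ns_s_ratio)
    }

    # structural events: at most one per gene
    u <- stats::runif(ng)
    ev_type <- ifelse(u < cfg$deletion_rate, "deletion",
                      ifelse(u < cfg$deletion_rate + cfg$tandem_dup_rate,
                             "tandem_dup", "none"))

    deleted <- which(ev_type == "deletion")
    deleted_span <- rep(FALSE, chrom_len)
    for (i in deleted) deleted_span[gene_abs[[i]]$start:gene_abs[[i]]$end] <- TRUE

    # ---- small variants -------------------------------------------------
    snp_pos <- which(stats::runif(chrom_len) < cfg$snp_rate)
    snp_pos <- snp_pos[!deleted_span[snp_pos]]
    indel_pos <- which(stats::runif(chrom_len) < cfg$indel_rate)
    indel_pos <- indel_pos[!deleted_span[indel_pos]]
    indel_pos <- indel_pos[indel_pos > 8L & indel_pos < chrom_len - 8L]

    # feature-region index (for indel containment checks)
    bounds <- sort(unique(c(1L, chrom_len + 1L,
                            unlist(lapply(gene_abs, function(g)
                              c(g$start, g$end + 1L,
                                g$exons$start, g$exons$end + 1L,
                                g$cds$start, g$cds$end + 1L))))))
    region_id <- function(x) findInterval(x, bounds)

    indels <- list()
    taken <- snp_pos  # occupied positions for spacing checks
    for (p0 in indel_pos) {
      placed <- FALSE
      pos <- p0
      for (try in 1:50) {
        L <- sample(1:6, 1)
        is_ins <- stats::runif(1) < 0.5
        ok <- if (is_ins) region_id(pos) == region_id(pos + 1L)
              else pos + L <= chrom_len && region_id(pos) == region_id(pos + L)
        ok <- ok && !deleted_span[pos] && !any(abs(taken - pos) <= 8L)
        if (ok) {
          indels[[length(indels) + 1]] <-
            list(pos = pos, len = L, ins = is_ins,
                 seq = if (is_ins) random_dna(L) else NULL)
          taken <- c(taken, pos + seq(0L, L))
          placed <- TRUE
          break
        }
        pos <- sample(seq(9L, chrom_len - 9L), 1)
      }
      if (!placed) stop("could not place indel without overlap after 50 redraws")
    }
    indel_anchor <- vapply(indels, function(x) x$pos, integer(1))
    if (length(indel_anchor))
      snp_pos <- snp_pos[!vapply(snp_pos, function(p)
        any(abs(indel_anchor - p) <= 8L), logical(1))]

    # SNP alleles, with NS:S rejection sampling inside CDS.  A rejected
    # missense proposal relocates to a free CDS position of the same
    # gene (staying put would defeat the rejection at positions whose
    # substitutions are all missense).
    occupied <- logical(chrom_len)
    occupied[snp_pos] <- TRUE
    blocked <- logical(chrom_len)
    for (x in indels) {
      blocked[max(1L, x$pos - 8L):min(chrom_len, x$pos + x$len + 8L)] <- TRUE
    }
    snps <- list()
    for (p0 in snp_pos) {
      pos <- p0
      if (region[pos] == "cds") {
        res <- NULL
        for (try in 1:100) {
          gi <- gene_of[pos]
          alt <- sample(setdiff(names(COMPLEMENT), chars[pos]), 1)
          cls <- classify_coding_snp(chars, cds_pos_list[[gi]],
                                     gene_abs[[gi]]$strand, pos, alt)
          keep <- if (cls == "missense") stats::runif(1) < accept_missense else TRUE
          if (keep) { res <- list(pos = pos, alt = alt, class = cls, gene = gi); break }
          for (r in 1:30) {
            cand <- resample(cds_pos_list[[gi]], 1)
            if (!occupied[cand] && !blocked[cand] && !deleted_span[cand]) {
              pos <- cand
              break
            }
          }
        }
        if (is.null(res)) next
        if (res$pos != p0) {
          occupied[p0] <- FALSE
          occupied[res$pos] <- TRUE
        }
        snps[[length(snps) + 1]] <- res
      } else {
        snps[[length(snps) + 1]] <-
          list(pos = pos, alt = sample(setdiff(names(COMPLEMENT), chars[pos]), 1),
               class = region[pos], gene = gene_of[pos])
      }
    }
    if (length(snps)) {  # dedupe positions after redraws
      keep <- !duplicated(vapply(snps, `[[`, integer(1), "pos"))
      snps <- snps[keep]
    }

    # ---- pass 1: apply SNPs, indels, gene deletions --------------------
    edits <- list()
    for (s in snps) edits[[length(edits) + 1]] <-
      list(kind = "snp", pos = s$pos, alt = s$alt)
    for (x in indels) edits[[length(edits) + 1]] <-
      if (x$ins) list(kind = "ins", pos = x$pos, seq = x$seq, len = x$len)
      else list(kind = "del", pos = x$pos, len = x$len)
    for (i in deleted) edits[[length(edits) + 1]] <-
      list(kind = "del", pos = gene_abs[[i]]$start - 1L,
           len = gene_abs[[i]]$end - gene_abs[[i]]$start + 1L,
           gene_del = TRUE)
    ord <- order(vapply(edits, `[[`, integer(1), "pos"))
    edits <- edits[ord]

    pieces <- character(0); cur <- 1L
    offset_events <- data.frame(after = integer(0), delta = integer(0))
    for (e in edits) {
      if (e$kind == "snp") {
        if (e$pos >= cur) {
          pieces <- c(pieces, substr(seqA, cur, e$pos - 1L), e$alt)
          cur <- e$pos + 1L
        }
      } else if (e$kind == "ins") {
        pieces <- c(pieces, substr(seqA, cur, e$pos), e$seq)
        cur <- e$pos + 1L
        offset_events <- rbind(offset_events,
                               data.frame(after = e$pos, delta = e$len))
      } else {  # deletion of pos+1 .. pos+len
        pieces <- c(pieces, substr(seqA, cur, e$pos))
        cur <- e$pos + e$len + 1L
        offset_events <- rbind(offset_events,
                               data.frame(after = e$pos + e$len, delta = -e$len))
      }
    }
    pieces <- c(pieces, substr(seqA, cur, chrom_len))
    seqB0 <- paste(pieces, collapse = "")

    map0 <- function(x) {
      x + vapply(x, function(xx)
        sum(offset_events$delta[offset_events$after < xx]), numeric(1))
    }

    # ---- pass 2: tandem duplications -----------------------------------
    dups <- which(ev_type == "tandem_dup")
    dup_events <- data.frame(after = integer(0), delta = integer(0))
    dup_info <- list()
    if (length(dups)) {
      # insert right-to-left so earlier B coordinates stay valid
      for (i in sort(dups, decreasing = TRUE)) {
        g <- gene_abs[[i]]
        bs <- map0(g$start); be <- map0(g$end)
        copy <- substr(seqB0, bs, be)
        # slight divergence of the duplicated copy
        cc <- strsplit(copy, "", fixed = TRUE)[[1]]
        nmut <- stats::rpois(1, length(cc) * 0.004)
        if (nmut > 0) {
          mp <- sample(length(cc), min(nmut, length(cc)))
          for (m in mp) cc[m] <- sample(setdiff(names(COMPLEMENT), cc[m]), 1)
          copy <- paste(cc, collapse = "")
        }
        seqB0 <- paste0(substr(seqB0, 1L, be), copy,
                        substr(seqB0, be + 1L, nchar(seqB0)))
        dup_events <- rbind(dup_events,
                            data.frame(after = g$end, delta = nchar(copy)))
        dup_info[[length(dup_info) + 1]] <-
          list(gene = i, b_insert_after = be, copy_len = nchar(copy))
      }
    }
    seqB <- seqB0
    all_events <- rbind(offset_events, dup_events)
    map_ab <- function(x) {
      x + vapply(x, function(xx)
        sum(all_events$delta[all_events$after < xx]), numeric(1))
    }

    # ---- genome B annotation -------------------------------------------
    b_ids <- sprintf("gB_%02d_%04d", ci, seq_len(ng))
    for (i in seq_len(ng)) {
      g <- gene_abs[[i]]
      row <- data.frame(gene_id = a_ids[i], chrom = chrom, start = g$start,
                        end = g$end, strand = g$strand,
                        stringsAsFactors = FALSE)
      genesA_rows[[length(genesA_rows) + 1]] <- row
      exonsA[[a_ids[i]]] <- g$exons
      cdsA[[a_ids[i]]] <- g$cds
      if (i %in% deleted) {
        pav[[length(pav) + 1]] <- data.frame(genome = "A", gene_id = a_ids[i],
                                             stringsAsFactors = FALSE)
        next
      }
      bmap <- function(df) data.frame(start = as.integer(map_ab(df$start)),
                                      end = as.integer(map_ab(df$end)))
      brow <- data.frame(gene_id = b_ids[i], chrom = chrom,
                         start = as.integer(map_ab(g$start)),
                         end = as.integer(map_ab(g$end)),
                         strand = g$strand, stringsAsFactors = FALSE)
      genesB_rows[[length(genesB_rows) + 1]] <- brow
      exonsB[[b_ids[i]]] <- bmap(g$exons)
      cdsB[[b_ids[i]]] <- bmap(g$cds)
      homolog[[length(homolog) + 1]] <-
        data.frame(a_gene_id = a_ids[i], b_gene_id = b_ids[i],
                   stringsAsFactors = FALSE)
    }
    # duplicated copies become extra genome-B genes
    for (d in dup_info) {
      i <- d$gene; g <- gene_abs[[i]]
      cid <- sprintf("gB_%02d_%04d_copy", ci, i)
      b_start <- as.integer(map_ab(g$start))
      rel <- function(df) data.frame(
        start = as.integer(map_ab(df$start)) - b_start + 1L,
        end = as.integer(map_ab(df$end)) - b_start + 1L)
      # map_ab uses strict "after < x", so the copy's own delta is excluded
      copy_start <- as.integer(map_ab(g$end)) + 1L
      crow <- data.frame(gene_id = cid, chrom = chrom,
                         start = copy_start,
                         end = copy_start + d$copy_len - 1L,
                         strand = g$strand, stringsAsFactors = FALSE)
      genesB_rows[[length(genesB_rows) + 1]] <- crow
      r_ex <- rel(g$exons); r_cd <- rel(g$cds)
      exonsB[[cid]] <- data.frame(start = r_ex$start + copy_start - 1L,
                                  end = r_ex$end + copy_start - 1L)
      cdsB[[cid]] <- data.frame(start = r_cd$start + copy_start - 1L,
                                end = r_cd$end + copy_start - 1L)
      paralogs[[length(paralogs) + 1]] <-
        data.frame(gene_id = cid, matched_b_gene_id = b_ids[i],
                   matched_a_gene_id = a_ids[i], stringsAsFactors = FALSE)
      sv_intervals[[length(sv_intervals) + 1]] <- data.frame(
        type = "tandem_dup", ref_chrom = chrom, ref_start = g$start,
        ref_end = g$end, qry_chrom = chrom,
        qry_start = as.integer(map_ab(g$start)),
        qry_end = copy_start + d$copy_len - 1L, stringsAsFactors = FALSE)
    }
    for (i in deleted) {
      g <- gene_abs[[i]]
      qpos <- as.integer(map_ab(g$start - 1L))
      sv_intervals[[length(sv_intervals) + 1]] <- data.frame(
        type = "deletion", ref_chrom = chrom, ref_start = g$start,
        ref_end = g$end, qry_chrom = chrom, qry_start = max(1L, qpos),
        qry_end = qpos + 1L, stringsAsFactors = FALSE)
    }

    # ---- blocks ---------------------------------------------------------
    struct_pts <- list()
    for (i in deleted) struct_pts[[length(struct_pts) + 1]] <-
      list(kind = "del", s = gene_abs[[i]]$start, e = gene_abs[[i]]$end)
    for (d in dup_info) struct_pts[[length(struct_pts) + 1]] <-
      list(kind = "dup", s = gene_abs[[d$gene]]$end, e = gene_abs[[d$gene]]$end)
    if (length(struct_pts)) {
      ordp <- order(vapply(struct_pts, `[[`, integer(1), "s"))
      struct_pts <- struct_pts[ordp]
    }
    a_start <- 1L
    seg_snp <- vapply(snps, `[[`, integer(1), "pos")
    emit_block <- function(s, e) {
      if (e < s + 50L) return(NULL)
      nsnp <- sum(seg_snp >= s & seg_snp <= e)
      idy <- max(90, round(100 * (1 - nsnp / (e - s + 1L)), 2))
      data.frame(ref_chrom = chrom, ref_start = s, ref_end = e,
                 qry_chrom = chrom, qry_start = as.integer(map_ab(s)),
                 qry_end = as.integer(map_ab(e)), identity = idy,
                 orientation = "forward", stringsAsFactors = FALSE)
    }
    for (sp in struct_pts) {
      if (sp$kind == "del") {
        b <- emit_block(a_start, sp$s - 1L)
        if (!is.null(b)) blocks[[length(blocks) + 1]] <- b
        a_start <- sp$e + 1L
      } else {
        b <- emit_block(a_start, sp$e)
        if (!is.null(b)) blocks[[length(blocks) + 1]] <- b
        a_start <- sp$e + 1L
      }
    }
    b <- emit_block(a_start, chrom_len)
    if (!is.null(b)) blocks[[length(blocks) + 1]] <- b

    # ---- variant table / truth -----------------------------------------
    for (s in snps) {
      variants[[length(variants) + 1]] <- data.frame(
        chrom = chrom, pos = s$pos, ref = chars[s$pos], alt = s$alt,
        kind = "snp", stringsAsFactors = FALSE)
      planted[[length(planted) + 1]] <- data.frame(
        chrom = chrom, pos = s$pos, ref = chars[s$pos], alt = s$alt,
        kind = "snp", effect_class = s$class,
        gene_id = if (is.na(s$gene)) NA_character_ else a_ids[s$gene],
        stringsAsFactors = FALSE)
    }
    for (x in indels) {
      if (x$ins) {
        ref <- chars[x$pos]; alt <- paste0(chars[x$pos], x$seq)
        kind <- "insertion"
      } else {
        ref <- substr(seqA, x$pos, x$pos + x$len)
        alt <- chars[x$pos]; kind <- "deletion"
      }
      cls <- if (region[x$pos] == "cds") {
        if (x$len %% 3L == 0L) {
          if (x$ins) "inframe_insertion" else "inframe_deletion"
        } else "frameshift"
      } else region[x$pos]
      variants[[length(variants) + 1]] <- data.frame(
        chrom = chrom, pos = x$pos, ref = ref, alt = alt, kind = kind,
        stringsAsFactors = FALSE)
      planted[[length(planted) + 1]] <- data.frame(
        chrom = chrom, pos = x$pos, ref = ref, alt = alt, kind = kind,
        effect_class = cls,
        gene_id = if (is.na(gene_of[x$pos])) NA_character_
                  else a_ids[gene_of[x$pos]],
        stringsAsFactors = FALSE)
    }

    genomeA[chrom] <- seqA
    genomeB[chrom] <- seqB
  }

  bind <- function(lst, empty) if (length(lst)) do.call(rbind, lst) else empty
  genesA_df <- bind(genesA_rows, NULL)
  genesB_df <- bind(genesB_rows, NULL)
  dnaA <- Biostrings::DNAStringSet(genomeA)
  dnaB <- Biostrings::DNAStringSet(genomeB)
  gsA <- gene_set(genesA_df, exonsA, cdsA, genome = dnaA)
  gsB <- gene_set(genesB_df, exonsB, cdsB, genome = dnaB)

  empty_var <- data.frame(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          kind = character(0), stringsAsFactors = FALSE)
  variants_df <- bind(variants, empty_var)
  if (nrow(variants_df))
    variants_df <- variants_df[order(variants_df$chrom, variants_df$pos), ]
  rownames(variants_df) <- NULL
  planted_df <- bind(planted, cbind(empty_var, effect_class = character(0),
                                    gene_id = character(0)))
  if (nrow(planted_df))
    planted_df <- planted_df[order(planted_df$chrom, planted_df$pos), ]
  rownames(planted_df) <- NULL

  structure(list(
    genome_a = list(seq = dnaA, genes = gsA),
    genome_b = list(seq = dnaB, genes = gsB),
    blocks = bind(blocks, NULL),
    variants = variants_df,
    sv_intervals = bind(sv_intervals, data.frame(
      type = character(0), ref_chrom = character(0), ref_start = integer(0),
      ref_end = integer(0), qry_chrom = character(0), qry_start = integer(0),
      qry_end = integer(0), stringsAsFactors = FALSE)),
    truth = list(
      homolog_map = bind(homolog, data.frame(a_gene_id = character(0),
                                             b_gene_id = character(0))),
      pav_genes = bind(pav, data.frame(genome = character(0),
                                       gene_id = character(0))),
      paralog_copies = bind(paralogs, data.frame(
        gene_id = character(0), matched_b_gene_id = character(0),
        matched_a_gene_id = character(0))),
      planted_variants = planted_df),
    config = cfg), class = "genome_pair_sim")
}

# Monte-Carlo estimate of the probability with which missense proposals
# must be accepted so that missense:silent matches the target in
# expectation.  Positions are sampled uniformly over the concatenated
# CDS space, matching the per-bp proposal distribution of SNP planting.
estimate_missense_acceptance <- function(chars, gene_abs, cds_pos_list,
                                         target, n = 20000L) {
  all_pos <- unlist(cds_pos_list, use.names = FALSE)
  gene_of_pos <- rep(seq_along(cds_pos_list), lengths(cds_pos_list))
  classes <- character(n)
  idx <- sample(length(all_pos), n, replace = TRUE)
  for (k in seq_len(n)) {
    gi <- gene_of_pos[idx[k]]
    pos <- all_pos[idx[k]]
    alt <- sample(setdiff(names(COMPLEMENT), chars[pos]), 1)
    classes[k] <- classify_coding_snp(chars, cds_pos_list[[gi]],
                                      gene_abs[[gi]]$strand, pos, alt)
  }
  p_syn <- mean(classes == "synonymous")
  p_mis <- mean(classes == "missense")
  if (p_mis == 0) return(1)
  min(1, target * p_syn / p_mis)
}

#' @export
print.genome_pair_sim <- function(x, ...) {
  cat("genome_pair_sim\n")
  cat(sprintf("  genome A: %d genes; genome B: %d genes\n",
              length(x$genome_a$genes), length(x$genome_b$genes)))
  cat(sprintf("  %d collinear blocks, %d small variants (%d SNPs)\n",
              nrow(x$blocks), nrow(x$variants),
              sum(x$variants$kind == "snp")))
  cat(sprintf("  truth: %d homolog pairs, %d PAV genes, %d paralog copies\n",
              nrow(x$truth$homolog_map), nrow(x$truth$pav_genes),
              nrow(x$truth$paralog_copies)))
  invisible(x)
}

#' Write a simulated genome pair to disk
#'
#' Emits FASTA + GFF3 for both genomes, the block table in the
#' `show-coords -T -H` tab dialect, the small-variant VCF (genome-A
#' coordinates), the structural-event interval table, and the truth
#' ledger as TSV.
#'
#' @param sim a `genome_pair_sim`.
#' @param dir output directory (created if missing).
#' @return invisibly, a named character vector of the written paths.
#' @export
write_genome_pair <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome_a_fasta = file.path(dir, "genomeA.fa"),
    genome_a_gff = file.path(dir, "genomeA.gff3"),
    genome_b_fasta = file.path(dir, "genomeB.fa"),
    genome_b_gff = file.path(dir, "genomeB.gff3"),
    coords = file.path(dir, "blocks.coords"),
    vcf = file.path(dir, "variants.vcf"),
    sv = file.path(dir, "sv_intervals.tsv"),
    truth_homologs = file.path(dir, "truth_homologs.tsv"),
    truth_pav = file.path(dir, "truth_pav.tsv"),
    truth_paralogs = file.path(dir, "truth_paralogs.tsv"),
    truth_variants = file.path(dir, "truth_variants.tsv"))
  write_genome_fasta(sim$genome_a$seq, paths["genome_a_fasta"])
  write_gff3(sim$genome_a$genes, paths["genome_a_gff"])
  write_genome_fasta(sim$genome_b$seq, paths["genome_b_fasta"])
  write_gff3(sim$genome_b$genes, paths["genome_b_gff"])
  write_coords(sim$blocks, paths["coords"])
  write_vcf(sim$variants, paths["vcf"],
            contigs = stats::setNames(Biostrings::width(sim$genome_a$seq),
                                      names(sim$genome_a$seq)))
  tsv <- function(df, p) utils::write.table(df, p, sep = "\t", quote = FALSE,
                                            row.names = FALSE)
  tsv(sim$sv_intervals, paths["sv"])
  tsv(sim$truth$homolog_map, paths["truth_homologs"])
  tsv(sim$truth$pav_genes, paths["truth_pav"])
  tsv(sim$truth$paralog_copies, paths["truth_paralogs"])
  tsv(sim$truth$planted_variants, paths["truth_variants"])
  invisible(paths)
}
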