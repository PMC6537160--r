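# Syntenic homolog assignment.
#
# Within each alignment block the two ordered gene lists are aligned by a
# global (Needleman-Wunsch) dynamic program whose match score is the
# transcript similarity score, so the assignment respects gene order.
# Genes outside every block are then classified against the whole other
# genome: no match above threshold -> presence/absence variant (PAV);
# best match already paired -> paralogous copy; best match unpaired ->
# rescued homolog pair.  Genes inside a block that the alignment leaves
# unpaired stay "unresolved in block" and are never counted as PAVs.

#' Genes contained in one alignment block
#'
#' A gene belongs to a block when at least half of its length overlaps the
#' block interval.  The list is ordered by position; for inverted blocks
#' the query-side list is returned reversed so that both lists run in the
#' same syntenic direction.
#'
#' @param gs a [gene_set].
#' @param block one row of a block table (see [parse_coords()]).
#' @param side `"ref"` or `"qry"`: which interval of the block to use.
#' @return character vector of gene ids, in syntenic order.
#' @export
genes_in_block <- function(gs, block, side = c("ref", "qry")) {
  side <- match.arg(side)
  chrom <- block[[paste0(side, "_chrom")]]
  bs <- block[[paste0(side, "_start")]]
  be <- block[[paste0(side, "_end")]]
  g <- gs$genes
  g <- g[g$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) return(character(0))
  ov <- pmin(g$end, be) - pmax(g$start, bs) + 1
  keep <- ov >= 0.5 * (g$end - g$start + 1)
  ids <- g$gene_id[keep][order(g$start[keep])]
  if (side == "qry" && identical(block$orientation, "inverted")) ids <- rev(ids)
  ids
}

#' Order-preserving alignment of two gene lists
#'
#' Global dynamic-programming alignment of the two gene sequences: a
#' matched pair contributes its similarity score, every gapped gene costs
#' `gap_penalty` (end gaps included).  Matched pairs whose similarity is
#' below `min_pair_similarity` are demoted to unresolved on both sides.
#' The result is monotone: pairs never cross.
#'
#' @param ref_ids,qry_ids character vectors of gene ids in syntenic order.
#' @param sim numeric similarity matrix with `ref_ids` rows and `qry_ids`
#'   columns (scores in \[0, 1\]).
#' @param gap_penalty non-negative gap cost per unpaired gene (default 0.2).
#' @param min_pair_similarity pairs below this similarity are demoted
#'   (default 0.3).
#' @return list with `pairs` (data.frame `ref_id`, `qry_id`, `score`),
#'   `unresolved_ref`, `unresolved_qry` (character vectors), and
#'   `total_score` (the DP objective before demotion).
#' @export
align_gene_lists <- function(ref_ids, qry_ids, sim, gap_penalty = 0.2,
                             min_pair_similarity = 0.3) {
  stopifnot(gap_penalty >= 0)
  n <- length(ref_ids); m <- length(qry_ids)
  if (n && m && (is.null(dim(sim)) || !all(dim(sim) == c(n, m)))) {
    stop("similarity matrix must be |ref| x |qry| for non-empty lists")
  }
  if (n == 0 || m == 0) {
    return(list(pairs = data.frame(ref_id = character(0),
                                   qry_id = character(0),
                                   score = numeric(0),
                                   stringsAsFactors = FALSE),
                unresolved_ref = ref_ids, unresolved_qry = qry_ids,
                total_score = -gap_penalty * (n + m)))
  }
  F <- matrix(0, n + 1, m + 1)
  F[, 1] <- -gap_penalty * (0:n)
  F[1, ] <- -gap_penalty * (0:m)
  ptr <- matrix(0L, n + 1, m + 1)  # 1 diag, 2 up (gap in qry), 3 left
  ptr[, 1] <- 2L; ptr[1, ] <- 3L; ptr[1, 1] <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      diag <- F[i, j] + sim[i, j]
      up <- F[i, j + 1] - gap_penalty
      left <- F[i + 1, j] - gap_penalty
      best <- max(diag, up, left)
      F[i + 1, j + 1] <- best
      # on exact ties prefer gap moves: traceback then pairs the
      # earliest-position genes among equal-scoring alternatives
      ptr[i + 1, j + 1] <- if (best == up) 2L else if (best == left) 3L
                           else 1L
    }
  }
  i <- n + 1L; j <- m + 1L
  ri <- integer(0); qj <- integer(0)
  while (i > 1L || j > 1L) {
    p <- ptr[i, j]
    if (p == 1L) { ri <- c(i - 1L, ri); qj <- c(j - 1L, qj); i <- i - 1L; j <- j - 1L }
    else if (p == 2L) i <- i - 1L
    else j <- j - 1L
  }
  scores <- sim[cbind(ri, qj)]
  keep <- scores >= min_pair_similarity
  pairs <- data.frame(ref_id = ref_ids[ri[keep]], qry_id = qry_ids[qj[keep]],
                      score = scores[keep], stringsAsFactors = FALSE)
  list(pairs = pairs,
       unresolved_ref = setdiff(ref_ids, pairs$ref_id),
       unresolved_qry = setdiff(qry_ids, pairs$qry_id),
       total_score = F[n + 1, m + 1])
}

# gene rank (order along its chromosome) lookup for a gene_set
gene_ranks <- function(gs) {
  g <- gs$genes
  rank <- integer(nrow(g)); names(rank) <- g$gene_id
  for (ch in unique(g$chrom)) {
    idx <- which(g$chrom == ch)
    rank[g$gene_id[idx[order(g$start[idx])]]] <- seq_along(idx)
  }
  rank
}

#' Classify genes that fall outside every alignment block
#'
#' Each unblocked gene is scored against the full set of other-genome
#' genes.  No match at or above `threshold` makes it a PAV; a best match
#' that is already homologously paired makes it a paralogous copy; an
#' unpaired best match founds a new ("rescued") homolog pair.  When
#' several candidates clear the threshold, a candidate lying within 10
#' genes of the paired homolog of either chromosomal neighbour of the
#' query gene gets a 10% multiplicative synteny bonus; remaining ties are
#' broken by gene-rank proximity to that expected syntenic position, then
#' by gene id.
#'
#' @param unblocked character vector of gene ids to classify (all from
#'   `own_gs`).
#' @param own_gs the [gene_set] the unblocked genes belong to.
#' @param other_gs the other genome's [gene_set] (candidate pool).
#' @param result a partially filled homology result list (fields `pairs`,
#'   `pav`, `paralog_copies`); updated entries are appended.
#' @param own_genome `"A"` or `"B"`, recorded in the PAV/paralog tables.
#' @param threshold minimum similarity score for a match (default 0.5).
#' @param provenance provenance label for rescued pairs.
#' @param sim optional precomputed similarity matrix (rows = `unblocked`,
#'   columns = all other-genome gene ids); computed from the transcripts
#'   when NULL.
#' @return the updated `result` list.
#' @export
classify_unblocked_genes <- function(unblocked, own_gs, other_gs, result,
                                     own_genome = "A", threshold = 0.5,
                                     provenance = "rescued_unblocked",
                                     sim = NULL) {
  if (!length(unblocked)) return(result)
  other_rank <- gene_ranks(other_gs)
  own_rank <- gene_ranks(own_gs)
  own_genes <- own_gs$genes
  pair_col_own <- if (own_genome == "A") "ref_id" else "qry_id"
  pair_col_other <- if (own_genome == "A") "qry_id" else "ref_id"

  if (is.null(sim)) {
    sim <- similarity_matrix(own_gs$transcript[unblocked],
                             other_gs$transcript)
  }

  for (gid in unblocked) {
    scores <- sim[gid, ]
    cand <- names(scores)[scores >= threshold]
    if (!length(cand)) {
      result$pav <- rbind(result$pav,
                          data.frame(genome = own_genome, gene_id = gid,
                                     stringsAsFactors = FALSE))
      next
    }
    # expected syntenic ranks: partners of the query's chromosomal neighbours
    grow <- own_genes[own_genes$gene_id == gid, ]
    chrom_ids <- own_genes$gene_id[own_genes$chrom == grow$chrom]
    chrom_ids <- chrom_ids[order(own_rank[chrom_ids])]
    pos <- match(gid, chrom_ids)
    neighbours <- chrom_ids[c(pos - 1L, pos + 1L)]
    neighbours <- neighbours[!is.na(neighbours)]
    partner_ranks <- numeric(0); partner_chrom <- character(0)
    for (nb in neighbours) {
      hit <- result$pairs[[pair_col_other]][result$pairs[[pair_col_own]] == nb]
      if (length(hit)) {
        partner_ranks <- c(partner_ranks, other_rank[[hit[1]]])
        partner_chrom <- c(partner_chrom,
                           other_gs$genes$chrom[other_gs$genes$gene_id == hit[1]])
      }
    }
    syn_dist <- vapply(cand, function(cd) {
      cr <- other_rank[[cd]]
      cchrom <- other_gs$genes$chrom[other_gs$genes$gene_id == cd]
      d <- Inf
      for (k in seq_along(partner_ranks)) {
        if (identical(cchrom, partner_chrom[k]))
          d <- min(d, abs(cr - partner_ranks[k]))
      }
      d
    }, numeric(1))
    eff <- scores[cand] * ifelse(syn_dist <= 10, 1.1, 1.0)
    ordc <- order(-eff, syn_dist, cand)
    best <- cand[ordc[1]]
    already <- best %in% result$pairs[[pair_col_other]]
    if (already) {
      result$paralog_copies <- rbind(result$paralog_copies,
        data.frame(genome = own_genome, gene_id = gid,
                   matched_gene_id = best, stringsAsFactors = FALSE))
    } else {
      new_pair <- if (own_genome == "A") {
        data.frame(ref_id = gid, qry_id = best, score = scores[[best]],
                   provenance = provenance, stringsAsFactors = FALSE)
      } else {
        data.frame(ref_id = best, qry_id = gid, score = scores[[best]],
                   provenance = provenance, stringsAsFactors = FALSE)
      }
      result$pairs <- rbind(result$pairs, new_pair)
    }
  }
  result
}

#' Completeness of one annotation against another genome
#'
#' A gene counts as mapped when some candidate reaches at least
#' `identity_min` identity and `coverage_min` coverage (both inclusive).
#' By default every cross pair is evaluated; supply `candidates` (a named
#' character vector, ref id -> candidate id) to restrict each gene to one
#' candidate, e.g. its assigned homolog.
#'
#' @param ref_gs [gene_set] whose genes are tested.
#' @param qry_gs [gene_set] providing the mapping targets.
#' @param candidates optional named map of ref gene id to qry gene id.
#' @param identity_min,coverage_min inclusive thresholds (0.90 / 0.85).
#' @return list with `fraction` (mapped / total), `mapped` (logical vector
#'   named by ref gene id).
#' @export
completeness_check <- function(ref_gs, qry_gs, candidates = NULL,
                               identity_min = 0.90, coverage_min = 0.85) {
  ids <- ref_gs$genes$gene_id
  mapped <- stats::setNames(logical(length(ids)), ids)
  for (gid in ids) {
    pool <- if (!is.null(candidates)) {
      if (is.na(candidates[gid]) || is.null(candidates[[gid]])) character(0)
      else candidates[[gid]]
    } else qry_gs$genes$gene_id
    for (cd in pool) {
      s <- transcript_similarity(ref_gs$transcript[[gid]],
                                 qry_gs$transcript[[cd]])
      if (s$identity_fraction >= identity_min &&
          s$coverage_fraction >= coverage_min) {
        mapped[gid] <- TRUE
        break
      }
    }
  }
  list(fraction = mean(mapped), mapped = mapped)
}

#' Align gene lists inside structural-variant intervals
#'
#' Applies the same order-preserving gene-list alignment used inside
#' syntenic blocks to the genes contained in each expansion/contraction
#' interval.  Pairs found here carry provenance `"sv_region"`; genes the
#' interval alignment leaves unpaired are returned as leftovers for pool
#' classification.
#'
#' @param sv_intervals data.frame with `ref_chrom`, `ref_start`, `ref_end`,
#'   `qry_chrom`, `qry_start`, `qry_end` (or NULL for no-op).
#' @param ref_gs,qry_gs the two [gene_set]s.
#' @param result a homology result list to append pairs to.
#' @param assigned_ref,assigned_qry gene ids already assigned elsewhere.
#' @param gap_penalty,min_pair_similarity see [align_gene_lists()].
#' @param ref_chrom_lengths,qry_chrom_lengths optional named chromosome
#'   lengths; an interval extending beyond its chromosome end is an error.
#' @return list with updated `result`, `assigned_ref`, `assigned_qry`, and
#'   `leftover_ref` / `leftover_qry` gene ids.
#' @export
classify_sv_region_genes <- function(sv_intervals, ref_gs, qry_gs,
                                     result = empty_homology_result(),
                                     assigned_ref = character(0),
                                     assigned_qry = character(0),
                                     gap_penalty = 0.2,
                                     min_pair_similarity = 0.3,
                                     ref_chrom_lengths = NULL,
                                     qry_chrom_lengths = NULL) {
  leftover_ref <- character(0); leftover_qry <- character(0)
  if (!is.null(sv_intervals) && nrow(sv_intervals)) {
    for (si in seq_len(nrow(sv_intervals))) {
      iv <- sv_intervals[si, ]
      if (iv$ref_start > iv$ref_end || iv$qry_start > iv$qry_end) {
        stop(sprintf("invalid SV interval at row %d", si))
      }
      if (!is.null(ref_chrom_lengths) &&
          iv$ref_end > ref_chrom_lengths[[iv$ref_chrom]]) {
        stop(sprintf("SV interval at row %d extends beyond the end of %s",
                     si, iv$ref_chrom))
      }
      if (!is.null(qry_chrom_lengths) &&
          iv$qry_end > qry_chrom_lengths[[iv$qry_chrom]]) {
        stop(sprintf("SV interval at row %d extends beyond the end of %s",
                     si, iv$qry_chrom))
      }
      fake_block <- data.frame(ref_chrom = iv$ref_chrom,
                               ref_start = iv$ref_start, ref_end = iv$ref_end,
                               qry_chrom = iv$qry_chrom,
                               qry_start = iv$qry_start, qry_end = iv$qry_end,
                               orientation = "forward",
                               stringsAsFactors = FALSE)
      r_ids <- setdiff(genes_in_block(ref_gs, fake_block, "ref"), assigned_ref)
      q_ids <- setdiff(genes_in_block(qry_gs, fake_block, "qry"), assigned_qry)
      r_ids <- setdiff(r_ids, result$unresolved_in_block$gene_id)
      q_ids <- setdiff(q_ids, result$unresolved_in_block$gene_id)
      if (length(r_ids) && length(q_ids)) {
        sim <- similarity_matrix(ref_gs$transcript[r_ids],
                                 qry_gs$transcript[q_ids])
        al <- align_gene_lists(r_ids, q_ids, sim, gap_penalty,
                               min_pair_similarity)
        if (nrow(al$pairs)) {
          al$pairs$provenance <- "sv_region"
          result$pairs <- rbind(result$pairs, al$pairs)
          assigned_ref <- c(assigned_ref, al$pairs$ref_id)
          assigned_qry <- c(assigned_qry, al$pairs$qry_id)
        }
        leftover_ref <- union(leftover_ref, al$unresolved_ref)
        leftover_qry <- union(leftover_qry, al$unresolved_qry)
      } else {
        leftover_ref <- union(leftover_ref, r_ids)
        leftover_qry <- union(leftover_qry, q_ids)
      }
    }
  }
  list(result = result, assigned_ref = assigned_ref,
       assigned_qry = assigned_qry, leftover_ref = leftover_ref,
       leftover_qry = leftover_qry)
}

empty_homology_result <- function() {
  list(pairs = data.frame(ref_id = character(0), qry_id = character(0),
                          score = numeric(0), provenance = character(0),
                          stringsAsFactors = FALSE),
       pav = data.frame(genome = character(0), gene_id = character(0),
                        stringsAsFactors = FALSE),
       paralog_copies = data.frame(genome = character(0),
                                   gene_id = character(0),
                                   matched_gene_id = character(0),
                                   stringsAsFactors = FALSE),
       unresolved_in_block = data.frame(genome = character(0),
                                        gene_id = character(0),
                                        stringsAsFactors = FALSE))
}

#' Genome-wide homolog assignment
#'
#' Runs the full classification: gene-order alignment inside every block,
#' the same alignment inside structural-variant intervals when supplied,
#' then pool classification of all remaining unblocked genes of both
#' genomes (PAV / paralogous copy / rescued pair).  Genes left unpaired
#' inside a block are reported as unresolved, never as PAVs.
#'
#' @param ref_gs,qry_gs the two annotated genomes ([gene_set]s).
#' @param blocks block table ([parse_coords()] layout).
#' @param sv_intervals optional structural-event intervals (columns
#'   `ref_chrom`, `ref_start`, `ref_end`, `qry_chrom`, `qry_start`,
#'   `qry_end`).
#' @param gap_penalty,min_pair_similarity see [align_gene_lists()].
#' @param unblocked_threshold minimum score for an unblocked match (0.5).
#' @return object of class `homology_result` with elements `pairs`, `pav`,
#'   `paralog_copies`, `unresolved_in_block`, and `params`.
#' @export
assign_homologs <- function(ref_gs, qry_gs, blocks, sv_intervals = NULL,
                            gap_penalty = 0.2, min_pair_similarity = 0.3,
                            unblocked_threshold = 0.5) {
  result <- empty_homology_result()
  assigned_ref <- character(0)  # genes no longer available for assignment
  assigned_qry <- character(0)
  blocked_ref <- character(0)   # genes falling inside any block
  blocked_qry <- character(0)

  if (!is.null(blocks) && nrow(blocks)) {
    for (bi in seq_len(nrow(blocks))) {
      block <- blocks[bi, ]
      r_ids <- setdiff(genes_in_block(ref_gs, block, "ref"), assigned_ref)
      q_ids <- setdiff(genes_in_block(qry_gs, block, "qry"), assigned_qry)
      blocked_ref <- union(blocked_ref, r_ids)
      blocked_qry <- union(blocked_qry, q_ids)
      if (!length(r_ids) && !length(q_ids)) next
      sim <- similarity_matrix(ref_gs$transcript[r_ids],
                               qry_gs$transcript[q_ids])
      al <- align_gene_lists(r_ids, q_ids, sim, gap_penalty,
                             min_pair_similarity)
      if (nrow(al$pairs)) {
        al$pairs$provenance <- "in_block"
        result$pairs <- rbind(result$pairs, al$pairs)
        assigned_ref <- c(assigned_ref, al$pairs$ref_id)
        assigned_qry <- c(assigned_qry, al$pairs$qry_id)
      }
      if (length(al$unresolved_ref)) {
        result$unresolved_in_block <- rbind(result$unresolved_in_block,
          data.frame(genome = "A", gene_id = al$unresolved_ref,
                     stringsAsFactors = FALSE))
      }
      if (length(al$unresolved_qry)) {
        result$unresolved_in_block <- rbind(result$unresolved_in_block,
          data.frame(genome = "B", gene_id = al$unresolved_qry,
                     stringsAsFactors = FALSE))
      }
    }
  }

  sv <- classify_sv_region_genes(sv_intervals, ref_gs, qry_gs, result,
                                 assigned_ref, assigned_qry,
                                 gap_penalty, min_pair_similarity)
  result <- sv$result
  assigned_ref <- sv$assigned_ref; assigned_qry <- sv$assigned_qry
  sv_leftover_ref <- sv$leftover_ref; sv_leftover_qry <- sv$leftover_qry

  unblocked_ref <- setdiff(ref_gs$genes$gene_id,
                           c(blocked_ref, assigned_ref))
  unblocked_qry <- setdiff(qry_gs$genes$gene_id,
                           c(blocked_qry, assigned_qry))
  sv_leftover_ref <- setdiff(sv_leftover_ref, assigned_ref)
  sv_leftover_qry <- setdiff(sv_leftover_qry, assigned_qry)
  unblocked_ref <- union(unblocked_ref, sv_leftover_ref)
  unblocked_qry <- union(unblocked_qry, sv_leftover_qry)

  result <- classify_unblocked_genes(sort(unblocked_ref), ref_gs, qry_gs,
                                     result, own_genome = "A",
                                     threshold = unblocked_threshold)
  result <- classify_unblocked_genes(sort(unblocked_qry), qry_gs, ref_gs,
                                     result, own_genome = "B",
                                     threshold = unblocked_threshold)

  result$params <- list(gap_penalty = gap_penalty,
                        min_pair_similarity = min_pair_similarity,
                        unblocked_threshold = unblocked_threshold)
  class(result) <- "homology_result"
  result
}

#' @export
print.homology_result <- function(x, ...) {
  cat("homology_result\n")
  cat(sprintf("  pairs       : %d (%s)\n", nrow(x$pairs),
              paste(sprintf("%s=%d", names(table(x$pairs$provenance)),
                            table(x$pairs$provenance)), collapse = ", ")))
  cat(sprintf("  PAV         : %d\n", nrow(x$pav)))
  cat(sprintf("  paralogs    : %d\n", nrow(x$paralog_copies)))
  cat(sprintf("  unresolved  : %d (in block, not PAV)\n",
              nrow(x$unresolved_in_block)))
  invisible(x)
}

#' @export
summary.homology_result <- function(object, ...) {
  c(pairs = nrow(object$pairs), pav = nrow(object$pav),
    paralog_copies = nrow(object$paralog_copies),
    unresolved_in_block = nrow(object$unresolved_in_block))
}

#' Write homology classification tables
#'
#' @param result a `homology_result`.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_homology_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(pairs = file.path(dir, "homolog_pairs.tsv"),
             pav = file.path(dir, "pav_genes.tsv"),
             paralogs = file.path(dir, "paralog_copies.tsv"),
             unresolved = file.path(dir, "unresolved_in_block.tsv"))
  utils::write.table(result$pairs, paths["pairs"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(result$pav, paths["pav"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(result$paralog_copies, paths["paralogs"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$unresolved_in_block, paths["unresolved"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
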