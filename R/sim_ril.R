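# RIL genotype simulator.
#
# The RIL genome is a fully homozygous mosaic of the two parental
# haplotypes (errors are injected separately, matching an inbred line
# whose residual heterozygosity is negligible).  Informative sites carry
# reference-parent allele 0 and other-parent allele 1; a configurable
# fraction of non-informative "dirty" sites (parents identical, reference
# parent polymorphic against its own assembly, heterozygous other parent)
# exercises the site filters.

#' Simulate a 3-sample RIL genotype table
#'
#' @param config a [sim_config()]; uses `n_breakpoints`,
#'   `genotype_error_rate`, `missing_rate`, and the seed.
#' @param parent_b_variants optional variant table (`chrom`, `pos`, `ref`,
#'   `alt`; SNP rows are used) giving the sites where the non-reference
#'   parent differs; when NULL, `n_sites` random sites are generated over
#'   `chrom_lengths`.
#' @param chrom_lengths named chromosome lengths; required when
#'   `parent_b_variants` is NULL.
#' @param n_sites number of informative sites to generate when no parent
#'   variant table is given (default 3000).
#' @param dirty_fraction fraction of extra non-informative sites of each
#'   kind (parents-identical, reference-parent polymorphism, heterozygous
#'   other parent) added to exercise the filters (default 0.02 each).
#' @param min_gap_sites minimum number of informative sites between
#'   consecutive breakpoints (and chromosome ends); breakpoint placement
#'   is re-drawn until satisfied (default 50).
#' @param breakpoint_quantum crossovers are placed in the gap following a
#'   multiple of this many informative sites (default 15, one analysis
#'   window), so a window-resolution detector can localise every planted
#'   crossover exactly; set to 1 to allow crossovers after any site.
#' @param sample_names names of the three samples in role order
#'   (reference parent, other parent, RIL).
#' @return list of class `ril_sim`: `variants` (with genotype columns),
#'   `truth` (`breakpoints` with the true crossover position and its
#'   flanking-site interval, `segments` giving the haplotype of every
#'   genomic interval, `n_informative`), and `sample_names`.
#' @export
simulate_ril_genotypes <- function(config, parent_b_variants = NULL,
                                   chrom_lengths = NULL, n_sites = 3000L,
                                   dirty_fraction = 0.02,
                                   min_gap_sites = 50L,
                                   breakpoint_quantum = 15L,
                                   sample_names = c("Rio", "BTx3197", "PR22")) {
  stopifnot(inherits(config, "sim_config"), length(sample_names) == 3)
  with_seed(derive_seed(config$seed, "ril"), {
    if (is.null(parent_b_variants)) {
      if (is.null(chrom_lengths)) {
        stop("supply chrom_lengths when parent_b_variants is NULL")
      }
      sites <- generate_sites(chrom_lengths, n_sites)
    } else {
      sites <- parent_b_variants[
        variant_kind(parent_b_variants$ref, parent_b_variants$alt) == "snp",
        c("chrom", "pos", "ref", "alt"), drop = FALSE]
      if (is.null(chrom_lengths)) {
        chrom_lengths <- tapply(sites$pos, sites$chrom, max) * 1.01
      }
    }
    if (!nrow(sites)) stop("zero informative sites: nothing to paint")
    sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
    rownames(sites) <- NULL

    # distribute breakpoints over chromosomes proportional to site counts
    site_counts <- table(sites$chrom)
    chroms <- names(site_counts)
    k_total <- config$n_breakpoints
    alloc <- stats::setNames(integer(length(chroms)), chroms)
    if (k_total > 0) {
      probs <- as.numeric(site_counts) / sum(site_counts)
      draw <- sample(chroms, k_total, replace = TRUE, prob = probs)
      tt <- table(draw)
      alloc[names(tt)] <- as.integer(tt)
    }

    truth_bp <- list(); segments <- list()
    hap <- character(nrow(sites))
    for (ch in chroms) {
      rows <- which(sites$chrom == ch)
      pos <- sites$pos[rows]
      S <- length(pos)
      k <- alloc[[ch]]
      bp_idx <- integer(0)
      if (k > 0) {
        gap <- max(min_gap_sites, breakpoint_quantum)
        # eligible cut indices: after a whole number of site groups, with
        # at least `gap` sites to each chromosome end
        eligible <- seq(breakpoint_quantum, S - 1L, by = breakpoint_quantum)
        eligible <- eligible[eligible >= gap & eligible <= S - gap]
        if (length(eligible) < k) {
          stop(sprintf("cannot place %d breakpoints on %s with %d sites (min gap %d, quantum %d)",
                       k, ch, S, min_gap_sites, breakpoint_quantum))
        }
        ok <- FALSE
        for (try in 1:1000) {
          cand <- sort(resample(eligible, k))
          if (k == 1 || all(diff(cand) >= gap)) { ok <- TRUE; break }
        }
        if (!ok) stop("breakpoint placement failed after 1000 redraws on ", ch)
        bp_idx <- cand
      }
      start_hap <- sample(c("R", "B"), 1)
      seg_hap <- rep(c(start_hap, setdiff(c("R", "B"), start_hap)),
                     length.out = length(bp_idx) + 1L)
      seg_of_site <- findInterval(seq_len(S), bp_idx + 1L) + 1L
      hap[rows] <- seg_hap[seg_of_site]
      bp_pos <- if (length(bp_idx)) {
        floor((pos[bp_idx] + pos[bp_idx + 1L]) / 2)
      } else integer(0)
      if (length(bp_idx)) {
        truth_bp[[length(truth_bp) + 1]] <- data.frame(
          chrom = ch, pos = bp_pos, left_site = pos[bp_idx],
          right_site = pos[bp_idx + 1L],
          left_hap = seg_hap[seq_along(bp_idx)],
          right_hap = seg_hap[seq_along(bp_idx) + 1L],
          stringsAsFactors = FALSE)
      }
      seg_bounds <- c(1L, bp_pos, as.integer(ceiling(chrom_lengths[[ch]])))
      segments[[length(segments) + 1]] <- data.frame(
        chrom = ch, start = seg_bounds[-length(seg_bounds)],
        end = seg_bounds[-1], hap = seg_hap, stringsAsFactors = FALSE)
    }
    empty_bp <- data.frame(chrom = character(0), pos = integer(0),
                           left_site = integer(0), right_site = integer(0),
                           left_hap = character(0), right_hap = character(0),
                           stringsAsFactors = FALSE)
    truth_bp <- if (length(truth_bp)) do.call(rbind, truth_bp) else empty_bp
    segments <- do.call(rbind, segments)

    gt_r <- rep("0/0", nrow(sites))
    gt_b <- rep("1/1", nrow(sites))
    gt_l <- ifelse(hap == "R", "0/0", "1/1")
    informative <- rep(TRUE, nrow(sites))

    # genotyping errors flip the RIL call to the other homozygote
    err <- stats::runif(nrow(sites)) < config$genotype_error_rate
    gt_l[err] <- ifelse(gt_l[err] == "0/0", "1/1", "0/0")

    variants <- cbind(sites, data.frame(gt_r, gt_b, gt_l,
                                        stringsAsFactors = FALSE))
    names(variants)[5:7] <- sample_names

    # dirty (non-informative) sites
    n_dirty <- round(nrow(sites) * dirty_fraction)
    if (n_dirty > 0) {
      dirty <- list()
      for (kind in c("parents_identical", "refparent_poly", "otherparent_het")) {
        d <- generate_sites(chrom_lengths, n_dirty)
        gts <- switch(kind,
          parents_identical = c("0/0", "0/0", "0/0"),
          refparent_poly = c("0/1", "1/1", "1/1"),
          otherparent_het = c("0/0", "0/1", "0/0"))
        d[sample_names[1]] <- gts[1]
        d[sample_names[2]] <- gts[2]
        d[sample_names[3]] <- gts[3]
        dirty[[kind]] <- d
      }
      variants <- rbind(variants, do.call(rbind, dirty))
    }

    # missing calls in any sample
    for (sn in sample_names) {
      miss <- stats::runif(nrow(variants)) < config$missing_rate
      variants[[sn]][miss] <- "./."
    }
    variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
    rownames(variants) <- NULL

    structure(list(variants = variants,
                   truth = list(breakpoints = truth_bp, segments = segments,
                                n_informative = sum(informative)),
                   sample_names = sample_names,
                   chrom_lengths = chrom_lengths),
              class = "ril_sim")
  })
}

generate_sites <- function(chrom_lengths, n_sites) {
  chroms <- names(chrom_lengths)
  lens <- as.numeric(chrom_lengths)
  per <- round(n_sites * lens / sum(lens))
  out <- list()
  for (k in seq_along(chroms)) {
    if (per[k] < 1) next
    pos <- sort(sample.int(as.integer(lens[k]), per[k]))
    ref <- sample(c("A", "C", "G", "T"), per[k], replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1))
    out[[k]] <- data.frame(chrom = chroms[k], pos = pos, ref = ref,
                           alt = alt, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' True parental background of genes under a simulated RIL
#'
#' Labels each gene by the haplotype of the segment containing its
#' midpoint.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @param ril a `ril_sim`.
#' @return named character vector ("R"/"B") indexed by gene id.
#' @export
ril_background_truth <- function(genes, ril) {
  seg <- ril$truth$segments
  out <- stats::setNames(character(nrow(genes)), genes$gene_id)
  for (i in seq_len(nrow(genes))) {
    mid <- (genes$start[i] + genes$end[i]) %/% 2
    s <- seg[seg$chrom == genes$chrom[i] & seg$start <= mid & seg$end >= mid, ]
    out[i] <- if (nrow(s)) s$hap[1] else NA_character_
  }
  out
}

#' Write a simulated RIL genotype table as VCF
#'
#' @param ril a `ril_sim`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ril_vcf <- function(ril, path) {
  gt <- as.matrix(ril$variants[, ril$sample_names, drop = FALSE])
  write_vcf(ril$variants[, c("chrom", "pos", "ref", "alt")], path,
            genotypes = gt,
            contigs = stats::setNames(as.integer(ceiling(ril$chrom_lengths)),
                                      names(ril$chrom_lengths)))
}

#' @export
print.ril_sim <- function(x, ...) {
  cat("ril_sim\n")
  cat(sprintf("  %d sites (%d informative), %d true breakpoints\n",
              nrow(x$variants), x$truth$n_informative,
              nrow(x$truth$breakpoints)))
  invisible(x)
}
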