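# RIL haplotype painting.
#
# Informative sites (parents called, reference parent homozygous-ref,
# other parent homozygous and different) are grouped into tumbling
# windows of 15 sites; the ratio of RIL alleles matching each parent
# calls the window R (> 2), B (< 0.25) or U (undetermined), and
# breakpoints are the intervals between adjacent determined windows with
# different calls.

#' Filter a 3-sample VCF down to informative sites
#'
#' A site survives when (i) all three genotypes are called, (ii) the
#' reference-parent sample is homozygous reference (a polymorphism
#' between that parent and its own reference assembly disqualifies the
#' site), (iii) the other parent is homozygous, and (iv) the two parents
#' differ.
#'
#' @param variants variant table with one genotype column per sample
#'   (see [read_vcf_variants()]).
#' @param samples named character vector mapping roles to sample names:
#'   `c(parent_r = ..., parent_b = ..., ril = ...)`; parent_r is the
#'   parent whose assembly is the alignment reference.
#' @return data.frame of class `informative_sites` with columns `chrom`,
#'   `pos`, `allele_r`, `allele_b`, `ril_gt` (allele-index genotype such
#'   as "0/0").
#' @export
filter_informative_sites <- function(variants,
                                     samples = c(parent_r = "Rio",
                                                 parent_b = "BTx3197",
                                                 ril = "PR22")) {
  missing_cols <- setdiff(samples, names(variants))
  if (length(missing_cols)) {
    stop(sprintf("sample(s) %s not in VCF; available columns: %s",
                 paste(missing_cols, collapse = ", "),
                 paste(names(variants), collapse = ", ")))
  }
  gt_r <- normalise_gt(variants[[samples[["parent_r"]]]])
  gt_b <- normalise_gt(variants[[samples[["parent_b"]]]])
  gt_l <- normalise_gt(variants[[samples[["ril"]]]])
  called <- !is.na(gt_r) & !is.na(gt_b) & !is.na(gt_l)
  r_homref <- gt_r == "0/0"
  b_hom <- gt_b %in% c("0/0", "1/1")
  differ <- gt_r != gt_b
  keep <- called & r_homref & b_hom & differ
  keep[is.na(keep)] <- FALSE
  v <- variants[keep, , drop = FALSE]
  gt_b <- gt_b[keep]; gt_l <- gt_l[keep]
  allele_b <- ifelse(gt_b == "1/1", v$alt, v$ref)
  out <- data.frame(chrom = v$chrom, pos = v$pos, allele_r = v$ref,
                    allele_b = allele_b, ril_gt = gt_l,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("informative_sites", "data.frame")
  out
}

# "0|0" -> "0/0", "./." and partial calls -> NA, order-normalise "1/0"
normalise_gt <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  gt[is.na(gt) | grepl("\\.", gt)] <- NA
  parts <- strsplit(gt, "/", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2 || anyNA(p)) return(NA_character_)
    paste(sort(p), collapse = "/")
  }, character(1))
}

#' Windowed parental-haplotype calls
#'
#' Consecutive non-overlapping (tumbling) groups of `window_size`
#' informative sites; trailing remainder sites are dropped.  Per window
#' the RIL alleles matching each parent are counted (2 per homozygous
#' genotype, 1 each for a heterozygous genotype); the ratio r/b calls the
#' window R when strictly greater than `r_threshold`, B when strictly
#' below `b_threshold`, otherwise U.  Pure windows are callable under the
#' zero-denominator convention (b = 0 with r > 0 is R; r = 0 with b > 0
#' is B).
#'
#' @param sites output of [filter_informative_sites()].
#' @param window_size sites per window (default 15).
#' @param r_threshold,b_threshold ratio thresholds (defaults 2 and 0.25).
#' @return data.frame with `chrom`, `window`, `start`, `end` (first/last
#'   site positions), `n_sites`, `r_alleles`, `b_alleles`, `proportion`,
#'   `call`.
#' @export
window_haplotype_calls <- function(sites, window_size = 15L,
                                   r_threshold = 2, b_threshold = 0.25) {
  out <- list()
  for (ch in unique(sites$chrom)) {
    s <- sites[sites$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    nwin <- nrow(s) %/% window_size
    if (nwin == 0) {
      warning(sprintf("chromosome %s has %d informative sites (< %d); no windows",
                      ch, nrow(s), window_size))
      next
    }
    for (w in seq_len(nwin)) {
      rows <- s[((w - 1L) * window_size + 1L):(w * window_size), ]
      counts <- count_parental_alleles(rows)
      r <- counts["r"]; b <- counts["b"]
      prop <- if (b > 0) r / b else Inf
      call <- if (b == 0 && r > 0) "R"
              else if (r == 0 && b > 0) "B"
              else if (prop > r_threshold) "R"
              else if (prop < b_threshold) "B"
              else "U"
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, window = w, start = min(rows$pos), end = max(rows$pos),
        n_sites = nrow(rows), r_alleles = unname(r), b_alleles = unname(b),
        proportion = unname(if (b > 0) r / b else Inf), call = call,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), window = integer(0),
                      start = integer(0), end = integer(0),
                      n_sites = integer(0), r_alleles = integer(0),
                      b_alleles = integer(0), proportion = numeric(0),
                      call = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Count RIL alleles matching each parent within one window.
count_parental_alleles <- function(rows) {
  r <- 0L; b <- 0L
  for (k in seq_len(nrow(rows))) {
    alleles <- strsplit(rows$ril_gt[k], "/", fixed = TRUE)[[1]]
    # allele index 0 is the reference-parent allele, 1 the other parent's
    r <- r + sum(alleles == "0")
    b <- b + sum(alleles == "1")
  }
  c(r = r, b = b)
}

#' Recombination breakpoints from windowed calls
#'
#' U windows are skipped; a breakpoint is emitted between each adjacent
#' pair of determined windows with different calls, its interval running
#' from the last site of the left window to the first site of the right
#' window (so an interleaved U window is absorbed into the interval).
#' Contiguous determined windows with the same call merge into haplotype
#' blocks spanning first to last site.
#'
#' @param windows output of [window_haplotype_calls()].
#' @return list with `breakpoints` (data.frame `chrom`, `start`, `end`,
#'   `left_call`, `right_call`) and `blocks` (data.frame `chrom`, `start`,
#'   `end`, `call`).
#' @export
call_breakpoints <- function(windows) {
  bps <- list(); blocks <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    w <- w[order(w$window), , drop = FALSE]
    det <- w[w$call %in% c("R", "B"), , drop = FALSE]
    if (!nrow(det)) next
    run_start <- 1L
    for (k in seq_len(nrow(det))) {
      last_in_run <- k == nrow(det) || det$call[k + 1L] != det$call[k]
      if (last_in_run) {
        blocks[[length(blocks) + 1]] <- data.frame(
          chrom = ch, start = det$start[run_start], end = det$end[k],
          call = det$call[k], stringsAsFactors = FALSE)
        if (k < nrow(det)) {
          bps[[length(bps) + 1]] <- data.frame(
            chrom = ch, start = det$end[k], end = det$start[k + 1L],
            left_call = det$call[k], right_call = det$call[k + 1L],
            stringsAsFactors = FALSE)
        }
        run_start <- k + 1L
      }
    }
  }
  empty_bp <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), left_call = character(0),
                         right_call = character(0), stringsAsFactors = FALSE)
  empty_bl <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), call = character(0),
                         stringsAsFactors = FALSE)
  list(breakpoints = if (length(bps)) do.call(rbind, bps) else empty_bp,
       blocks = if (length(blocks)) do.call(rbind, blocks) else empty_bl)
}

#' Write haplotype blocks as BED
#'
#' BED is 0-based half-open; internal coordinates are 1-based inclusive,
#' so `start - 1` is the only conversion applied.
#'
#' @param blocks `blocks` element from [call_breakpoints()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_blocks_bed <- function(blocks, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", blocks$chrom,
                   as.integer(blocks$start) - 1L, as.integer(blocks$end),
                   blocks$call)
  writeLines(lines, path)
  invisible(path)
}
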