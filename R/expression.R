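# Genotype-by-time differential expression with background assignment.
#
# The per-gene decision structure mirrors the count-based analysis it
# stands in for: median-of-ratios size factors, a log2 variance-reducing
# transform, and an F-test of the genotype x stage interaction against
# the additive model, at a raw p < 0.001 (no FDR step).

#' Size factors and variance-stabilising transform
#'
#' Size factor = median across genes of count / geometric-mean count
#' (genes containing any zero are excluded from the median).  If every
#' gene contains a zero, total-count scaling is used with a warning.
#' Transformed value = log2(count / size_factor + 1).
#'
#' @param counts integer matrix, genes x samples.
#' @return list with `vst` (transformed matrix) and `size_factors`
#'   (named numeric vector).
#' @export
size_factors_and_vst <- function(counts) {
  counts <- as.matrix(counts)
  if (any(colSums(counts) <= 0)) stop("every sample must have positive total")
  nonzero <- rowSums(counts == 0) == 0
  if (!any(nonzero)) {
    warning("all genes contain a zero; falling back to total-count scaling")
    sf <- colSums(counts) / mean(colSums(counts))
  } else {
    log_gm <- rowMeans(log(counts[nonzero, , drop = FALSE]))
    sf <- apply(counts[nonzero, , drop = FALSE], 2, function(cnt)
      exp(stats::median(log(cnt) - log_gm)))
  }
  vst <- log2(sweep(counts, 2, sf, "/") + 1)
  list(vst = vst, size_factors = sf)
}

check_design <- function(samples, tissue) {
  s <- samples[samples$tissue == tissue, , drop = FALSE]
  if (!nrow(s)) stop("no samples for tissue: ", tissue)
  tab <- table(s$genotype, s$stage)
  if (any(tab < 2)) {
    bad <- which(tab < 2, arr.ind = TRUE)[1, ]
    stop(sprintf("design cell %s x %s has < 2 replicates in tissue %s",
                 rownames(tab)[bad[1]], colnames(tab)[bad[2]], tissue))
  }
  s
}

#' Per-gene genotype-by-time interaction test
#'
#' For one tissue, fits per gene a two-way fixed-effects linear model of
#' the transformed counts on genotype, stage, and their interaction, and
#' reports the F-test of the interaction terms against the additive
#' model.  The residual projections are shared across genes (one QR
#' decomposition per model), so the test is vectorised over the whole
#' matrix.  Genes with zero variance within the tissue are excluded and
#' flagged.
#'
#' @param counts integer matrix, genes x samples.
#' @param samples data.frame with columns `sample`, `genotype`, `tissue`,
#'   `stage`, `replicate`; `sample` must match `colnames(counts)`.
#' @param tissue tissue to test.
#' @param alpha significance threshold on the raw p-value (default 0.001).
#' @return data.frame with `gene_id`, `tissue`, `gxt_pvalue`,
#'   `significant`, `flag` ("ok" or "zero_variance").
#' @export
interaction_test <- function(counts, samples, tissue, alpha = 0.001) {
  s <- check_design(samples, tissue)
  counts <- as.matrix(counts)
  sub <- counts[, s$sample, drop = FALSE]
  vst <- size_factors_and_vst(sub)$vst
  geno <- factor(s$genotype)
  stage <- factor(s$stage, levels = unique(s$stage))
  X_add <- stats::model.matrix(~ geno + stage)
  X_full <- stats::model.matrix(~ geno * stage)
  Y <- t(vst)
  rss <- function(X) {
    Q <- qr.Q(qr(X))
    R <- Y - Q %*% (t(Q) %*% Y)
    colSums(R^2)
  }
  rss_add <- rss(X_add)
  rss_full <- rss(X_full)
  df_int <- ncol(X_full) - ncol(X_add)
  df_res <- nrow(Y) - ncol(X_full)
  f <- ((rss_add - rss_full) / df_int) / (rss_full / df_res)
  p <- stats::pf(f, df_int, df_res, lower.tail = FALSE)
  # degenerate genes: constant raw counts, or no residual variation
  zero_var <- apply(sub, 1, function(y) stats::var(y) == 0) |
    apply(vst, 1, function(y) stats::var(y) == 0)
  p[zero_var] <- NA
  data.frame(gene_id = rownames(counts), tissue = tissue,
             gxt_pvalue = unname(p),
             significant = !is.na(p) & p < alpha,
             flag = ifelse(zero_var, "zero_variance", "ok"),
             stringsAsFactors = FALSE)
}

#' Assign genes to parental backgrounds
#'
#' A gene fully inside an R haplotype block is on the RIO background,
#' fully inside a B block on the BTX background; genes overlapping a
#' breakpoint interval, a U gap, or a chromosome with no blocks are
#' SPANNING.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @param blocks haplotype blocks (`chrom`, `start`, `end`, `call`) from
#'   [call_breakpoints()].
#' @return named character vector (RIO / BTX / SPANNING) indexed by
#'   gene id.
#' @export
assign_background <- function(genes, blocks) {
  out <- stats::setNames(rep("SPANNING", nrow(genes)), genes$gene_id)
  warned <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    bl <- blocks[blocks$chrom == g$chrom, , drop = FALSE]
    if (!nrow(bl)) {
      if (!(g$chrom %in% warned)) {
        warning("no haplotype blocks on chromosome ", g$chrom,
                "; genes there are SPANNING")
        warned <- c(warned, g$chrom)
      }
      next
    }
    inside <- bl$start <= g$start & bl$end >= g$end
    if (any(inside)) {
      out[i] <- if (bl$call[which(inside)[1]] == "R") "RIO" else "BTX"
    }
  }
  out
}

#' Background-filtered DEG counts and percentages
#'
#' Per tissue: total significant DEGs, the number retained after removing
#' genes with identical genetic backgrounds in both genotypes (retained =
#' background BTX, i.e. different alleles), and the retained percentage
#' truncated to one decimal.  SPANNING genes are excluded from both the
#' numerator and the denominator.  With zero significant DEGs the
#' percentage is undefined (NA), not 0.
#'
#' @param degs data.frame with `gene_id`, `tissue`, `significant`, and
#'   `background` columns.
#' @param background_fraction optional genome-wide BTX gene fraction for
#'   the independence comparison; included in the result when given.
#' @return data.frame with `tissue`, `total_degs`, `retained`,
#'   `retained_pct`, `retained_fraction`; attribute
#'   `genome_btx_percent` when `background_fraction` is supplied.
#' @export
background_filter_report <- function(degs, background_fraction = NULL) {
  out <- list()
  for (ts in unique(degs$tissue)) {
    d <- degs[degs$tissue == ts & degs$significant, , drop = FALSE]
    d <- d[d$background %in% c("RIO", "BTX"), , drop = FALSE]
    total <- nrow(d)
    retained <- sum(d$background == "BTX")
    out[[length(out) + 1]] <- data.frame(
      tissue = ts, total_degs = total, retained = retained,
      retained_pct = if (total > 0) percent_1dp(retained / total) else NA_real_,
      retained_fraction = if (total > 0) retained / total else NA_real_,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(background_fraction)) {
    attr(res, "genome_btx_percent") <- percent_1dp(background_fraction)
  }
  res
}

#' Retained percentage from printed counts
#'
#' The percentage arithmetic applied to a (total, retained) pair of DEG
#' counts: exact integer counts, one truncation-to-one-decimal step.
#'
#' @param total,retained DEG counts.
#' @return percentage with one decimal (NA when `total` is 0).
#' @export
retained_percent <- function(total, retained) {
  ifelse(total > 0, percent_1dp(retained / total), NA_real_)
}

#' Temporal expression-pattern labels
#'
#' Per genotype, stage means of the transformed counts are computed and
#' consecutive-stage changes discretised to up/down/flat at
#' `threshold` transformed units; the label is the path string, e.g.
#' "flat-up-down-flat".
#'
#' @param vst transformed matrix, genes x samples.
#' @param samples sample sheet (see [interaction_test()]).
#' @param tissue tissue whose samples are used.
#' @param threshold discretisation threshold in transformed units
#'   (default 1.0).
#' @return data.frame with `gene_id`, `genotype`, `path`, `peak_stage`
#'   (stage label of a single interior peak, else NA), plus the per-stage
#'   mean columns `mean.<stage>`.
#' @export
pattern_groups <- function(vst, samples, tissue, threshold = 1.0) {
  s <- samples[samples$tissue == tissue, , drop = FALSE]
  stages <- unique(s$stage)
  if (length(stages) < 3) stop("need >= 3 ordered stages")
  out <- list()
  for (gt in unique(s$genotype)) {
    means <- sapply(stages, function(st) {
      cols <- s$sample[s$genotype == gt & s$stage == st]
      rowMeans(vst[, cols, drop = FALSE])
    })
    if (is.null(dim(means))) means <- matrix(means, nrow = 1,
                                             dimnames = list(rownames(vst),
                                                             stages))
    d <- means[, -1, drop = FALSE] - means[, -ncol(means), drop = FALSE]
    steps <- ifelse(d >= threshold, "up", ifelse(d <= -threshold, "down",
                                                 "flat"))
    path <- apply(steps, 1, paste, collapse = "-")
    peak <- apply(steps, 1, function(st) {
      k <- which(st == "up")
      # single interior peak: up into a stage and down out of it
      for (x in k) if (x < length(st) && st[x + 1] == "down")
        return(stages[x + 1])
      NA_character_
    })
    df <- data.frame(gene_id = rownames(vst), genotype = gt, path = path,
                     peak_stage = peak, stringsAsFactors = FALSE)
    colnames(means) <- paste0("mean.", stages)
    out[[length(out) + 1]] <- cbind(df, means)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Does a pattern peak at a given stage?
#'
#' @param patterns output of [pattern_groups()].
#' @param stage stage label.
#' @param genotype optional genotype filter.
#' @return logical vector over the (filtered) pattern rows.
#' @export
peak_at <- function(patterns, stage, genotype = NULL) {
  p <- patterns
  if (!is.null(genotype)) p <- p[p$genotype == genotype, , drop = FALSE]
  !is.na(p$peak_stage) & p$peak_stage == stage
}

#' Per-stage fold changes (reference genotype over RIL)
#'
#' Ratio of normalised mean counts at each stage, reference genotype over
#' the RIL genotype.  A zero denominator yields NA (flagged undefined),
#' never infinity.
#'
#' @param counts genes x samples count matrix.
#' @param samples sample sheet.
#' @param tissue tissue to use.
#' @param gene gene id.
#' @param numerator,denominator genotype labels (defaults "Rio", "PR22").
#' @return data.frame with `stage`, `fold_change`, `undefined`.
#' @export
stage_fold_changes <- function(counts, samples, tissue, gene,
                               numerator = "Rio", denominator = "PR22") {
  s <- samples[samples$tissue == tissue, , drop = FALSE]
  norm <- sweep(as.matrix(counts[, s$sample, drop = FALSE]), 2,
                size_factors_and_vst(counts[, s$sample, drop = FALSE])$size_factors,
                "/")
  stages <- unique(s$stage)
  fc <- numeric(length(stages)); undef <- logical(length(stages))
  for (k in seq_along(stages)) {
    num_cols <- s$sample[s$genotype == numerator & s$stage == stages[k]]
    den_cols <- s$sample[s$genotype == denominator & s$stage == stages[k]]
    num <- mean(norm[gene, num_cols])
    den <- mean(norm[gene, den_cols])
    if (den == 0) { fc[k] <- NA_real_; undef[k] <- TRUE }
    else fc[k] <- num / den
  }
  data.frame(stage = stages, fold_change = fc, undefined = undef,
             stringsAsFactors = FALSE)
}
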