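# Normalisation, the interaction F-test against a per-gene lm oracle,
# background assignment, the report arithmetic, patterns, fold changes.

make_expr <- function(seed, n_genes = 400, de_fraction = 0, n_tissues = 1,
                      ...) {
  cfg <- sim_config(seed = seed, de_fraction = de_fraction,
                    n_tissues = n_tissues, ...)
  bg <- stats::setNames(rep(c("R", "B"), length.out = n_genes),
                        sprintf("g%05d", seq_len(n_genes)))
  list(cfg = cfg, expr = simulate_expression(cfg, bg), bg = bg)
}

test_that("size factors follow the median-of-ratios definition", {
  counts <- matrix(rpois(200, 50) + 1L, 20, 10,
                   dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  # identical samples: all size factors 1
  same <- counts[, c(1, 1, 1)]
  colnames(same) <- c("a", "b", "c")
  sf <- size_factors_and_vst(same)$size_factors
  expect_equal(unname(sf), c(1, 1, 1))
  # doubling every gene doubles the size factor
  doubled <- cbind(a = counts[, 1], b = 2L * counts[, 1])
  sf2 <- size_factors_and_vst(doubled)$size_factors
  expect_equal(unname(sf2["b"] / sf2["a"]), 2)
  # transform is strictly increasing in the count at fixed size factor
  v <- size_factors_and_vst(doubled)$vst
  ord <- order(doubled[, "a"])
  expect_true(all(diff(v[ord, "a"]) >= 0))
  # all-zero-containing genes: fallback with warning
  z <- counts; z[cbind(1:20, rep(1:10, 2))] <- 0L
  expect_warning(size_factors_and_vst(z), "total-count")
  bad <- counts; bad[, 1] <- 0L
  expect_error(size_factors_and_vst(bad), "positive total")
})

test_that("interaction F-test equals the per-gene anova(lm) route", {
  m <- make_expr(seed = 301, n_genes = 50)
  res <- interaction_test(m$expr$counts, m$expr$samples, "internode")
  s <- m$expr$samples
  vst <- size_factors_and_vst(m$expr$counts[, s$sample])$vst
  for (g in rownames(vst)[c(1, 10, 25, 50)]) {
    d <- data.frame(y = vst[g, ], geno = s$genotype,
                    stage = factor(s$stage, levels = unique(s$stage)))
    a <- stats::anova(stats::lm(y ~ geno * stage, d))
    expect_equal(res$gxt_pvalue[res$gene_id == g],
                 a["geno:stage", "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("constant genes are excluded with a flag, thin designs fail", {
  m <- make_expr(seed = 302, n_genes = 30)
  counts <- m$expr$counts
  counts["g00001", ] <- 7L
  res <- interaction_test(counts, m$expr$samples, "internode")
  expect_true(is.na(res$gxt_pvalue[res$gene_id == "g00001"]))
  expect_equal(res$flag[res$gene_id == "g00001"], "zero_variance")
  expect_false(res$significant[res$gene_id == "g00001"])

  thin <- m$expr$samples[m$expr$samples$replicate == 1 |
                           m$expr$samples$genotype == "Rio", ]
  expect_error(interaction_test(counts[, thin$sample], thin, "internode"),
               "< 2 replicates")
})

test_that("null type-I rate at p < 0.001 is calibrated (small run)", {
  m <- make_expr(seed = 303, n_genes = 3000)
  res <- interaction_test(m$expr$counts, m$expr$samples, "internode")
  rate <- mean(res$gxt_pvalue < 0.001, na.rm = TRUE)
  # generous 3-SD band for the reduced gene count used in the unit test
  expect_lt(rate, 0.001 + 3 * sqrt(0.001 * 0.999 / 3000))
})

test_that("backgrounds come from block containment only", {
  genes <- data.frame(gene_id = c("in_r", "in_b", "straddle", "lost"),
                      chrom = c("chr01", "chr01", "chr01", "chr99"),
                      start = c(100L, 5100L, 3900L, 10L),
                      end = c(900L, 5900L, 4300L, 90L),
                      stringsAsFactors = FALSE)
  blocks <- data.frame(chrom = "chr01", start = c(1L, 5000L),
                       end = c(4000L, 9000L), call = c("R", "B"),
                       stringsAsFactors = FALSE)
  expect_warning(bg <- assign_background(genes, blocks), "chr99")
  expect_equal(unname(bg[c("in_r", "in_b", "straddle", "lost")]),
               c("RIO", "BTX", "SPANNING", "SPANNING"))
})

test_that("background-filter arithmetic reproduces the printed percentages", {
  expect_equal(retained_percent(1686, 820), 48.6)
  expect_equal(retained_percent(156, 119), 76.2)
  # the recomputed leaf value (the tool reports 43.6; see vignette)
  expect_equal(retained_percent(1220, 533), 43.6)
  expect_true(is.na(retained_percent(0, 0)))

  mk_degs <- function(tissue, n_btx, n_rio, n_span = 3) {
    data.frame(gene_id = sprintf("%s%04d", tissue, seq_len(n_btx + n_rio +
                                                             n_span)),
               tissue = tissue, significant = TRUE,
               background = c(rep("BTX", n_btx), rep("RIO", n_rio),
                              rep("SPANNING", n_span)),
               stringsAsFactors = FALSE)
  }
  degs <- rbind(mk_degs("internode", 820, 1686 - 820),
                mk_degs("meristem", 119, 156 - 119))
  rep_tbl <- background_filter_report(degs, background_fraction = 0.474)
  i <- rep_tbl[rep_tbl$tissue == "internode", ]
  expect_equal(i$total_degs, 1686)   # SPANNING rows excluded
  expect_equal(i$retained, 820)
  expect_equal(i$retained_pct, 48.6)
  mrow <- rep_tbl[rep_tbl$tissue == "meristem", ]
  expect_equal(mrow$retained_pct, 76.2)
  expect_equal(attr(rep_tbl, "genome_btx_percent"), 47.4)

  none <- data.frame(gene_id = "g", tissue = "leaf", significant = FALSE,
                     background = "BTX", stringsAsFactors = FALSE)
  r0 <- background_filter_report(none)
  expect_true(is.na(r0$retained_pct))
})

test_that("pattern paths and peaks follow the discretisation rule", {
  stages <- c("VEG", "RI", "FL", "ANT", "SD")
  samples <- expand.grid(replicate = 1:2, stage = stages,
                         genotype = c("Rio", "PR22"),
                         stringsAsFactors = FALSE)
  samples$tissue <- "internode"
  samples$sample <- sprintf("%s_%s_r%d", samples$genotype, samples$stage,
                            samples$replicate)
  means <- c(2, 2, 5, 2, 2)
  vst <- matrix(0, 2, nrow(samples),
                dimnames = list(c("peaky", "rising"), samples$sample))
  for (k in seq_along(stages)) {
    cols <- samples$sample[samples$stage == stages[k]]
    vst["peaky", cols] <- means[k]
    vst["rising", cols] <- c(1, 3, 5, 7, 9)[k]
  }
  pat <- pattern_groups(vst, samples, "internode", threshold = 1.0)
  peaky <- pat[pat$gene_id == "peaky" & pat$genotype == "Rio", ]
  expect_equal(peaky$path, "flat-up-down-flat")
  expect_equal(peaky$peak_stage, "FL")
  expect_true(peak_at(pat[pat$gene_id == "peaky", ], "FL", "Rio"))
  rising <- pat[pat$gene_id == "rising" & pat$genotype == "PR22", ]
  expect_equal(rising$path, "up-up-up-up")
  expect_true(is.na(rising$peak_stage))
  expect_error(pattern_groups(vst, samples[samples$stage %in%
                                             stages[1:2], ], "internode"),
               ">= 3")
})

test_that("planted temporal patterns are recovered from noisy counts", {
  m <- make_expr(seed = 304, n_genes = 2000, de_fraction = 0.1,
                 de_effect_log2fc = 2, nb_dispersion = 0.05)
  vst <- size_factors_and_vst(m$expr$counts)$vst
  pat <- pattern_groups(vst, m$expr$samples, "internode")
  de <- m$expr$truth$de_genes
  sel <- de$gene_id[de$pattern == "peakFL_ril_peakANT_ref" &
                      de$tissue == "internode"]
  expect_gte(length(sel), 20)
  ril_rows <- pat[pat$genotype == "PR22" & pat$gene_id %in% sel, ]
  ref_rows <- pat[pat$genotype == "Rio" & pat$gene_id %in% sel, ]
  expect_gte(mean(peak_at(ril_rows, "FL")), 0.9)
  expect_gte(mean(peak_at(ref_rows, "ANT")), 0.9)
})

test_that("stage fold changes are ratios of normalised means, NA on zero", {
  m <- make_expr(seed = 305, n_genes = 12)
  counts <- m$expr$counts
  s <- m$expr$samples
  # make every sample column identical so size factors are exactly 1
  counts[] <- rep(counts[, 1], ncol(counts))
  # then craft one gene: Rio mean 8, PR22 mean 2 at every stage
  counts["g00001", s$genotype == "Rio"] <- 8L
  counts["g00001", s$genotype == "PR22"] <- 2L
  counts["g00002", ] <- 5L
  counts["g00003", s$genotype == "PR22"] <- 0L
  fc <- stage_fold_changes(counts, s, "internode", "g00001")
  expect_equal(fc$fold_change, rep(4, 5))
  fc2 <- stage_fold_changes(counts, s, "internode", "g00002")
  expect_equal(fc2$fold_change, rep(1, 5))
  fc3 <- stage_fold_changes(counts, s, "internode", "g00003")
  expect_true(all(is.na(fc3$fold_change)))
  expect_true(all(fc3$undefined))
})
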