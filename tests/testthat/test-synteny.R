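# Block parsing, transcript similarity, gene-order alignment, and the
# unblocked / SV-region / completeness classification rules.

test_that("parse_coords reads the tab dialect and normalises inverted rows", {
  path <- tempfile()
  writeLines(c("1\t10000\t1\t9950\t10000\t9950\t98.5\tchr1\tchr1",
               "20000\t30000\t30500\t20500\t10001\t10001\t97.0\tchr1\tchr1"),
             path)
  b <- parse_coords(path)
  expect_equal(nrow(b), 2)
  expect_equal(b$orientation, c("forward", "inverted"))
  expect_equal(b$ref_start[1], 1); expect_equal(b$ref_end[1], 10000)
  expect_equal(b$qry_start[2], 20500); expect_equal(b$qry_end[2], 30500)

  bad <- tempfile()
  writeLines(c("1\t10\t1\t10\t10\t10\t99.0\tchr1\tchr1",
               "1\t2\t3\t4\t5\t6\t7.0\tchr1"), bad)
  expect_error(parse_coords(bad), "line 2")

  empty <- tempfile(); writeLines(character(0), empty)
  expect_warning(res <- parse_coords(empty), "empty")
  expect_equal(nrow(res), 0)
})

test_that("coords round-trip through write_coords and parse_coords", {
  blocks <- data.frame(ref_chrom = "chr01", ref_start = c(1L, 500L),
                       ref_end = c(400L, 900L), qry_chrom = "chr01",
                       qry_start = c(1L, 480L), qry_end = c(390L, 880L),
                       identity = c(99.12, 98.5),
                       orientation = c("forward", "inverted"),
                       stringsAsFactors = FALSE)
  path <- tempfile()
  write_coords(blocks, path)
  back <- parse_coords(path)
  expect_equal(back$ref_start, blocks$ref_start)
  expect_equal(back$qry_start, blocks$qry_start)
  expect_equal(back$orientation, blocks$orientation)
})

test_that("transcript similarity: identity, prefix coverage, random bound", {
  s <- paste(rep(c("A", "C", "G", "T"), 100), collapse = "")
  expect_equal(transcript_similarity(s, s)$score, 1.0)

  # exact 50% prefix: coverage is defined on the shorter sequence
  half <- substr(s, 1, 200)
  r <- transcript_similarity(s, half)
  expect_equal(r$identity_fraction, 1.0)
  expect_equal(r$coverage_fraction, 1.0)
  expect_equal(r$score, 1.0)

  expect_error(transcript_similarity("", s), "non-empty")

  set.seed(202)
  for (k in 1:100) {
    a <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
    expect_lt(transcript_similarity(a, b)$score, 0.5)
  }
})

test_that("similarity_matrix agrees with pairwise transcript_similarity", {
  set.seed(7)
  mk <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                          collapse = "")
  ref <- stats::setNames(vapply(c(120, 200, 150), mk, character(1)),
                         c("r1", "r2", "r3"))
  qry <- stats::setNames(c(ref[["r2"]], mk(180)), c("q1", "q2"))
  m <- similarity_matrix(ref, qry)
  for (i in names(ref)) for (j in names(qry)) {
    expect_equal(m[i, j], transcript_similarity(ref[[i]], qry[[j]])$score,
                 tolerance = 1e-9)
  }
})

test_that("genes_in_block applies the 50% overlap rule and inversion", {
  gs <- toy_gene_set(c("g1", "g2", "g3"), "chr01",
                     starts = c(100L, 950L, 2000L),
                     ends = c(500L, 1150L, 2400L))
  block <- data.frame(ref_chrom = "chr01", ref_start = 1L, ref_end = 1000L,
                      qry_chrom = "chr01", qry_start = 1L, qry_end = 1000L,
                      orientation = "forward", stringsAsFactors = FALSE)
  # g1 fully inside; g2 overlaps 51/201 (~25%) -> out; g3 outside
  expect_equal(genes_in_block(gs, block, "ref"), "g1")
  block$ref_end <- block$qry_end <- 1100L  # g2 now 151/201 (~75%) -> in
  expect_equal(genes_in_block(gs, block, "ref"), c("g1", "g2"))
  block$orientation <- "inverted"
  expect_equal(genes_in_block(gs, block, "qry"), c("g2", "g1"))
})

test_that("gene-list alignment reproduces hand-derived pairings", {
  # identical 4-gene lists under an identity similarity matrix
  ids <- paste0("g", 1:4)
  sim <- diag(4); dimnames(sim) <- list(ids, ids)
  al <- align_gene_lists(ids, ids, sim)
  expect_equal(nrow(al$pairs), 4)
  expect_equal(al$total_score, 4.0)
  expect_equal(al$pairs$ref_id, al$pairs$qry_id)

  # ref (g1,g2,g3) vs qry (h1,h3): g2 has no counterpart
  sim2 <- matrix(0.05, 3, 2, dimnames = list(c("g1", "g2", "g3"),
                                             c("h1", "h3")))
  sim2["g1", "h1"] <- 0.9; sim2["g3", "h3"] <- 0.8
  al2 <- align_gene_lists(c("g1", "g2", "g3"), c("h1", "h3"), sim2,
                          gap_penalty = 0.2)
  expect_setequal(paste(al2$pairs$ref_id, al2$pairs$qry_id),
                  c("g1 h1", "g3 h3"))
  expect_equal(al2$unresolved_ref, "g2")
  expect_equal(al2$total_score,
               brute_force_alignment_score(sim2, 0.2), tolerance = 1e-12)

  # empty query: everything unresolved
  al3 <- align_gene_lists(c("g1", "g2"), character(0),
                          matrix(numeric(0), 2, 0))
  expect_equal(al3$unresolved_ref, c("g1", "g2"))
  expect_equal(nrow(al3$pairs), 0)

  expect_error(align_gene_lists(c("g1"), c("h1"), matrix(1, 2, 2)),
               "similarity matrix")
})

test_that("DP alignment equals exhaustive enumeration on random instances", {
  set.seed(11)
  for (k in 1:200) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    sim <- matrix(round(stats::runif(n * m), 3), n, m,
                  dimnames = list(paste0("r", seq_len(n)),
                                  paste0("q", seq_len(m))))
    gap <- sample(c(0.1, 0.2, 0.4), 1)
    al <- align_gene_lists(rownames(sim), colnames(sim), sim,
                           gap_penalty = gap, min_pair_similarity = 0)
    expect_equal(al$total_score, brute_force_alignment_score(sim, gap),
                 tolerance = 1e-9)
  }
})

test_that("alignment pairs are monotone in both lists", {
  set.seed(23)
  for (k in 1:25) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    sim <- matrix(stats::runif(n * m), n, m,
                  dimnames = list(paste0("r", seq_len(n)),
                                  paste0("q", seq_len(m))))
    al <- align_gene_lists(rownames(sim), colnames(sim), sim,
                           min_pair_similarity = 0)
    ri <- match(al$pairs$ref_id, rownames(sim))
    qi <- match(al$pairs$qry_id, colnames(sim))
    expect_true(all(diff(ri) > 0))
    expect_true(all(diff(qi) > 0))
  }
})

test_that("unblocked classification follows the threshold and pairing rules", {
  own <- toy_gene_set("x1", "chr01", 100L, 400L)
  other <- toy_gene_set(c("y1", "y2"), "chr01", c(100L, 900L),
                        c(400L, 1200L))
  res <- empty_result <- syntril:::empty_homology_result()

  # best score below 0.5 -> PAV
  sim <- matrix(c(0.4, 0.1), 1, 2, dimnames = list("x1", c("y1", "y2")))
  r1 <- classify_unblocked_genes("x1", own, other, res, own_genome = "A",
                                 sim = sim)
  expect_equal(r1$pav$gene_id, "x1")

  # score 0.8 to an already-paired gene -> paralogous copy
  res2 <- empty_result
  res2$pairs <- data.frame(ref_id = "z9", qry_id = "y1", score = 0.9,
                           provenance = "in_block", stringsAsFactors = FALSE)
  sim2 <- matrix(c(0.8, 0.1), 1, 2, dimnames = list("x1", c("y1", "y2")))
  r2 <- classify_unblocked_genes("x1", own, other, res2, own_genome = "A",
                                 sim = sim2)
  expect_equal(r2$paralog_copies$gene_id, "x1")
  expect_equal(r2$paralog_copies$matched_gene_id, "y1")

  # unpaired best match -> rescued homolog pair
  sim3 <- matrix(c(0.2, 0.8), 1, 2, dimnames = list("x1", c("y1", "y2")))
  r3 <- classify_unblocked_genes("x1", own, other, empty_result,
                                 own_genome = "A", sim = sim3)
  expect_equal(r3$pairs$ref_id, "x1")
  expect_equal(r3$pairs$qry_id, "y2")
  expect_equal(r3$pairs$provenance, "rescued_unblocked")
})

test_that("synteny weighting promotes the neighbourhood candidate", {
  # query gene x2 sits between x1 and x3; x1 is paired with y05.
  # candidate y06 (rank 6, within 10 of y05) scores 0.6; candidate y20
  # (rank 20, outside) scores 0.62: 0.6 * 1.1 = 0.66 > 0.62.
  own <- toy_gene_set(c("x1", "x2", "x3"), "chr01",
                      starts = c(100L, 600L, 1100L),
                      ends = c(400L, 900L, 1400L))
  other_ids <- sprintf("y%02d", 1:20)
  other <- toy_gene_set(other_ids, "chr01",
                        starts = seq(100L, by = 500L, length.out = 20),
                        ends = seq(400L, by = 500L, length.out = 20))
  res <- syntril:::empty_homology_result()
  res$pairs <- data.frame(ref_id = "x1", qry_id = "y05", score = 0.9,
                          provenance = "in_block", stringsAsFactors = FALSE)
  sim <- matrix(0, 1, 20, dimnames = list("x2", other_ids))
  sim["x2", "y06"] <- 0.6
  sim["x2", "y20"] <- 0.62
  r <- classify_unblocked_genes("x2", own, other, res, own_genome = "A",
                                sim = sim)
  new_pair <- r$pairs[r$pairs$ref_id == "x2", ]
  expect_equal(new_pair$qry_id, "y06")
})

test_that("SV-region alignment pairs by position and flags leftovers", {
  # tandem duplication: ref (g) vs qry (h1, h2) with identical transcripts
  tx <- paste(rep("ACGT", 60), collapse = "")
  ref <- toy_gene_set("g", "chr01", 100L, 339L,
                      transcripts = c(g = tx))
  qry <- toy_gene_set(c("h1", "h2"), "chr01", c(100L, 500L), c(339L, 739L),
                      transcripts = c(h1 = tx, h2 = tx))
  sv <- data.frame(ref_chrom = "chr01", ref_start = 1L, ref_end = 400L,
                   qry_chrom = "chr01", qry_start = 1L, qry_end = 800L,
                   stringsAsFactors = FALSE)
  out <- classify_sv_region_genes(sv, ref, qry)
  expect_equal(nrow(out$result$pairs), 1)
  expect_equal(out$result$pairs$qry_id, "h1")  # position tie-break
  expect_equal(out$result$pairs$provenance, "sv_region")
  expect_equal(out$leftover_qry, "h2")

  # empty interval: nothing happens
  sv0 <- sv; sv0$ref_start <- 5000L; sv0$ref_end <- 5100L
  sv0$qry_start <- 5000L; sv0$qry_end <- 5100L
  out0 <- classify_sv_region_genes(sv0, ref, qry)
  expect_equal(nrow(out0$result$pairs), 0)
  expect_equal(length(out0$leftover_ref), 0)

  # interval beyond the chromosome end fails when lengths are known
  expect_error(classify_sv_region_genes(sv, ref, qry,
                                        ref_chrom_lengths = c(chr01 = 350L)),
               "beyond the end")
})

test_that("completeness thresholds are inclusive on both margins", {
  base <- strsplit(paste(rep("ACGT", 50), collapse = ""), "")[[1]]  # 200 nt
  # exactly 90% identity: 20 isolated interior mismatches
  mism <- base
  flip <- function(x) c(A = "C", C = "A", G = "T", T = "G")[[x]]
  idx <- seq(11, by = 9, length.out = 20)
  for (i in idx) mism[i] <- flip(mism[i])
  s_ident <- transcript_similarity(paste(base, collapse = ""),
                                   paste(mism, collapse = ""))
  expect_equal(s_ident$identity_fraction, 0.90, tolerance = 1e-9)
  expect_equal(s_ident$coverage_fraction, 1.0)

  full <- paste(base, collapse = "")
  ref_gs <- toy_gene_set("a", "chr01", 1L, 200L, transcripts = c(a = full))

  qry_ok <- toy_gene_set("b", "chr01", 1L, 200L,
                         transcripts = c(b = paste(mism, collapse = "")))
  cc <- completeness_check(ref_gs, qry_ok, candidates = c(a = "b"))
  expect_true(cc$mapped[["a"]])   # identity exactly 0.90, coverage 1

  qry_low <- toy_gene_set("b", "chr01", 1L, 160L,
                          transcripts = c(b = paste(base[1:160], collapse = "")))
  cc2 <- completeness_check(ref_gs, qry_low, candidates = c(a = "b"))
  expect_true(cc2$mapped[["a"]])  # identity 1, coverage 1 of shorter

  # high identity but low coverage of the shorter sequence: not mapped
  scrambled <- vapply(base[101:200], flip, character(1))
  qry_cov <- toy_gene_set("b", "chr01", 1L, 200L,
                          transcripts = c(b = paste(c(base[1:100], scrambled),
                                                    collapse = "")))
  cc3 <- completeness_check(ref_gs, qry_cov, candidates = c(a = "b"))
  expect_false(cc3$mapped[["a"]])
})

test_that("homology recovers simulated truth and keeps the partition", {
  cfg <- sim_config(seed = 5, n_chromosomes = 2, genes_per_chromosome = 15,
                    tandem_dup_rate = 0.08, deletion_rate = 0.08)
  sim <- simulate_genome_pair(cfg)
  hom <- assign_homologs(sim$genome_a$genes, sim$genome_b$genes, sim$blocks,
                         sv_intervals = sim$sv_intervals)
  truth <- sim$truth
  rec <- mean(paste(truth$homolog_map$a_gene_id, truth$homolog_map$b_gene_id)
              %in% paste(hom$pairs$ref_id, hom$pairs$qry_id))
  expect_gte(rec, 0.95)
  expect_setequal(hom$pav$gene_id,
                  truth$pav_genes$gene_id)
  expect_setequal(hom$paralog_copies$gene_id, truth$paralog_copies$gene_id)

  # partition: every gene of both genomes in exactly one category
  for (side in c("A", "B")) {
    gs <- if (side == "A") sim$genome_a$genes else sim$genome_b$genes
    ids <- gs$genes$gene_id
    col <- if (side == "A") hom$pairs$ref_id else hom$pairs$qry_id
    counts <- (ids %in% col) +
      (ids %in% hom$pav$gene_id[hom$pav$genome == side]) +
      (ids %in% hom$paralog_copies$gene_id[hom$paralog_copies$genome == side]) +
      (ids %in% hom$unresolved_in_block$gene_id[hom$unresolved_in_block$genome == side])
    expect_true(all(counts == 1), label = paste("genome", side))
  }
})

test_that("raising the unblocked threshold never decreases the PAV count", {
  cfg <- sim_config(seed = 13, n_chromosomes = 1, genes_per_chromosome = 12,
                    deletion_rate = 0.15, tandem_dup_rate = 0.05)
  sim <- simulate_genome_pair(cfg)
  pav_counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(thr) {
    hom <- assign_homologs(sim$genome_a$genes, sim$genome_b$genes,
                           sim$blocks, unblocked_threshold = thr)
    nrow(hom$pav)
  }, numeric(1))
  expect_true(all(diff(pav_counts) >= 0))
})
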