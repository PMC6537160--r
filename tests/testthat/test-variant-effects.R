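# Codon-aware SNP classification against a full-translation oracle,
# indel frame arithmetic, positional classes, and windowed densities.

test_that("a crafted CDS gives the expected effect and impact classes", {
  # CDS: ATG GGG AAA TAA ; single exon, plus strand
  cr <- crafted_gene_chrom("ATGGGGAAATAA", strand = "+")
  cds0 <- cr$cds_range[1]
  mk <- function(pos, ref, alt) data.frame(chrom = "chrT", pos = pos,
                                           ref = ref, alt = alt,
                                           stringsAsFactors = FALSE)
  seqc <- cr$seq
  at <- function(p) substr(seqc, p, p)

  # GGG -> GGA: synonymous, LOW
  p <- cds0 + 5L  # third base of codon 2
  eff <- annotate_variants(mk(p, at(p), "A"), cr$gs, cr$genome)
  expect_equal(eff$effect, "synonymous")
  expect_equal(eff$impact, "LOW")
  expect_equal(eff$protein_change, "G2G")

  # GGG -> GAG: missense, MODERATE
  p <- cds0 + 4L
  eff <- annotate_variants(mk(p, at(p), "A"), cr$gs, cr$genome)
  expect_equal(eff$effect, "missense")
  expect_equal(eff$impact, "MODERATE")

  # AAA -> TAA: stop gained, HIGH
  p <- cds0 + 6L
  eff <- annotate_variants(mk(p, at(p), "T"), cr$gs, cr$genome)
  expect_equal(eff$effect, "stop_gained")
  expect_equal(eff$impact, "HIGH")

  # ATG -> CTG: start lost, HIGH
  eff <- annotate_variants(mk(cds0, at(cds0), "C"), cr$gs, cr$genome)
  expect_equal(eff$effect, "start_lost")

  # TAA -> CAA: stop lost, HIGH
  p <- cds0 + 9L
  eff <- annotate_variants(mk(p, at(p), "C"), cr$gs, cr$genome)
  expect_equal(eff$effect, "stop_lost")

  # 3-bp in-frame insertion inside the CDS: MODERATE
  p <- cds0 + 4L
  eff <- annotate_variants(mk(p, at(p), paste0(at(p), "CGG")), cr$gs,
                           cr$genome)
  expect_equal(eff$effect, "inframe_insertion")
  expect_equal(eff$impact, "MODERATE")

  # ref mismatch is an error naming the position
  expect_error(annotate_variants(mk(cds0, "N", "A"), cr$gs, cr$genome),
               "mismatch at chrT")
})

test_that("positional classes: utr, intron-free gene, flanks, intergenic", {
  cr <- crafted_gene_chrom("ATGGGGAAATAA", strand = "+", pad = 6000L)
  seqc <- cr$seq
  at <- function(p) substr(seqc, p, p)
  mk <- function(pos) data.frame(chrom = "chrT", pos = pos, ref = at(pos),
                                 alt = if (at(pos) == "A") "G" else "A",
                                 stringsAsFactors = FALSE)
  g <- cr$gs$genes
  eff <- annotate_variants(mk(g$start + 2L), cr$gs, cr$genome)   # 5' UTR
  expect_equal(eff$effect, "utr")
  expect_equal(eff$impact, "MODIFIER")
  eff <- annotate_variants(mk(g$start - 100L), cr$gs, cr$genome)
  expect_equal(eff$effect, "upstream")
  eff <- annotate_variants(mk(g$end + 100L), cr$gs, cr$genome)
  expect_equal(eff$effect, "downstream")
  eff <- annotate_variants(mk(g$end + 5500L), cr$gs, cr$genome)
  expect_equal(eff$effect, "intergenic")

  # minus-strand gene: flanks swap
  crm <- crafted_gene_chrom("ATGGGGAAATAA", strand = "-", pad = 6000L)
  gm <- crm$gs$genes
  seqm <- crm$seq
  mkm <- function(pos) data.frame(chrom = "chrT", pos = pos,
                                  ref = substr(seqm, pos, pos),
                                  alt = if (substr(seqm, pos, pos) == "A")
                                    "G" else "A",
                                  stringsAsFactors = FALSE)
  eff <- annotate_variants(mkm(gm$start - 100L), crm$gs, crm$genome)
  expect_equal(eff$effect, "downstream")
  eff <- annotate_variants(mkm(gm$end + 100L), crm$gs, crm$genome)
  expect_equal(eff$effect, "upstream")
})

test_that("SNP classification matches the full-translation oracle on sampled sites", {
  # the exhaustive both-strand scan lives in the acceptance suite; here a
  # random sample of CDS substitutions from two genes guards the same
  # agreement cheaply
  cfg <- sim_config(seed = 77, n_chromosomes = 1, genes_per_chromosome = 2,
                    gene_codons_range = c(60L, 80L), snp_rate = 0,
                    indel_rate = 0, tandem_dup_rate = 0, deletion_rate = 0)
  sim <- simulate_genome_pair(cfg)
  gs <- sim$genome_a$genes
  chrom_seq <- as.character(sim$genome_a$seq[["chr01"]])
  bases <- c("A", "C", "G", "T")
  set.seed(78)
  for (gid in gs$genes$gene_id) {
    segs <- gs$cds[[gid]]
    cds_pos <- unlist(Map(seq, segs$start, segs$end), use.names = FALSE)
    pick <- sort(sample(cds_pos, 40))
    vars <- do.call(rbind, lapply(pick, function(p) {
      ref <- substr(chrom_seq, p, p)
      data.frame(chrom = "chr01", pos = p, ref = ref,
                 alt = sample(setdiff(bases, ref), 1),
                 stringsAsFactors = FALSE)
    }))
    ann <- annotate_variants(vars, gs, sim$genome_a$seq)
    oracle <- vapply(seq_len(nrow(vars)), function(i)
      oracle_snp_effect(chrom_seq, gs, gid, vars$pos[i], vars$alt[i]),
      character(1))
    expect_identical(ann$effect, oracle, label = gid)
  }
})

test_that("indels are frameshift exactly when length is not a multiple of 3", {
  cr <- crafted_gene_chrom(paste(c("ATG", rep("GGA", 30), "TAA"),
                                 collapse = ""))
  seqc <- cr$seq
  p <- cr$cds_range[1] + 10L  # interior CDS position
  for (L in 1:9) {
    ins <- data.frame(chrom = "chrT", pos = p, ref = substr(seqc, p, p),
                      alt = paste0(substr(seqc, p, p),
                                   paste(rep("A", L), collapse = "")),
                      stringsAsFactors = FALSE)
    del <- data.frame(chrom = "chrT", pos = p,
                      ref = substr(seqc, p, p + L),
                      alt = substr(seqc, p, p), stringsAsFactors = FALSE)
    for (v in list(ins, del)) {
      eff <- annotate_variants(v, cr$gs, cr$genome)
      if (L %% 3 != 0) {
        expect_equal(eff$effect, "frameshift")
        expect_equal(eff$impact, "HIGH")
      } else {
        expect_true(eff$effect %in% c("inframe_insertion",
                                      "inframe_deletion"))
        expect_equal(eff$impact, "MODERATE")
      }
    }
  }
})

test_that("per-gene missense:silent summary follows the counting rules", {
  eff <- data.frame(
    gene_id = c(rep("g1", 5), rep("g2", 2), "g3", NA),
    effect = c("missense", "missense", "missense", "synonymous", "synonymous",
               "missense", "intron", "synonymous", "missense"),
    stringsAsFactors = FALSE)
  s <- gene_effect_summary(eff)
  g1 <- s$per_gene[s$per_gene$gene_id == "g1", ]
  expect_equal(g1$missense_count, 3)
  expect_equal(g1$silent_count, 2)
  expect_equal(g1$ratio, 1.5)
  # g2: one missense, zero silent -> infinite ratio, still flagged
  g2 <- s$per_gene[s$per_gene$gene_id == "g2", ]
  expect_equal(g2$ratio, Inf)
  expect_setequal(s$genes_ratio_gt1, c("g1", "g2"))
  # g3: 0 missense 1 silent -> ratio 0, not flagged
  expect_false("g3" %in% s$genes_ratio_gt1)
  expect_equal(s$overall_ratio, 4 / 3)
})

test_that("planted NS:S ratio is recovered by the annotator within 15%", {
  cfg <- sim_config(seed = 55, n_chromosomes = 1,
                    genes_per_chromosome = 150, snp_rate = 0.05,
                    indel_rate = 0, tandem_dup_rate = 0, deletion_rate = 0,
                    target_ns_s_ratio = 1.1, spacer_range = c(200L, 500L))
  sim <- simulate_genome_pair(cfg)
  eff <- annotate_variants(sim$variants, sim$genome_a$genes,
                           sim$genome_a$seq)
  n_coding <- sum(eff$effect %in% c("missense", "synonymous"))
  expect_gte(n_coding, 1000)
  ratio <- gene_effect_summary(eff)$overall_ratio
  expect_lt(abs(ratio - 1.1) / 1.1, 0.15)
})

test_that("SNP density windows scale by width and conserve totals", {
  # chromosome of 1.6 Mb: one full 1-Mb window, one trailing 600-kb window
  vars <- data.frame(chrom = "chr01",
                     pos = as.integer(c(round(seq(1, 999001,
                                                  length.out = 1000)),
                                        round(seq(1000001, 1.6e6,
                                                  length.out = 300)))),
                     ref = "A", alt = "G", kind = "snp",
                     stringsAsFactors = FALSE)
  d <- snp_density_windows(vars, c(chr01 = 1.6e6), window = 1e6, step = 1e6)
  # 1 Mb window with 1000 SNPs -> density 200 per 200 kb
  expect_equal(d$n_snps[1], 1000)
  expect_equal(d$density[1], 200)
  # trailing 600-kb window with 300 SNPs -> scaled by actual width: 100
  expect_equal(d$end[2] - d$start[2] + 1, 6e5)
  expect_equal(d$n_snps[2], 300)
  expect_equal(d$density[2], 100)
  # conservation at step == window
  expect_equal(sum(d$n_snps), nrow(vars))

  # empty window is zero
  v2 <- data.frame(chrom = "c", pos = 1500001L, ref = "A", alt = "G",
                   kind = "snp", stringsAsFactors = FALSE)
  d2 <- snp_density_windows(v2, c(c = 1.6e6), window = 1e6, step = 1e6)
  expect_equal(d2$n_snps, c(0, 1))
  expect_equal(d2$density[1], 0)

  # sliding windows overlap: step 200 kb, each SNP counted in up to 5 windows
  d3 <- snp_density_windows(vars, c(chr01 = 1.6e6))
  expect_equal(d3$start, seq(1, 1.6e6, by = 2e5))
})
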