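test_that("the generator is deterministic under a fixed seed", {
  g1 <- simulate_genome(n_chrom = 1, chrom_length = 20000, seed = 17)
  g2 <- simulate_genome(n_chrom = 1, chrom_length = 20000, seed = 17)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$sitemap, g2$sitemap)
  des <- sim_design(seed = 17, n_sites = 500)
  smp <- simulate_site_positions(500, seed = 17)
  c1 <- simulate_counts(smp, des, sim_effects())
  c2 <- simulate_counts(smp, des, sim_effects())
  expect_identical(c1$counts$counts, c2$counts$counts)
  lv <- matrix(0.5, nrow(g1$sitemap), 1, dimnames = list(NULL, "S1"))
  r1 <- simulate_reads(g1$genome, g1$sitemap, lv, seed = 3)
  r2 <- simulate_reads(g1$genome, g1$sitemap, lv, seed = 3)
  expect_identical(r1$reads, r2$reads)
})

test_that("planted CCGG motifs are exactly what the digest recovers", {
  g <- simulate_genome(n_chrom = 2, chrom_length = 50000,
                       ccgg_rate = 1 / 250, seed = 23)
  sm <- find_ccgg_sites(g$genome)
  expect_identical(sm$chrom, g$sitemap$chrom)
  expect_identical(sm$pos, g$sitemap$pos)
  g0 <- simulate_genome(n_chrom = 1, chrom_length = 20000,
                        ccgg_rate = 0, seed = 23)
  expect_equal(nrow(find_ccgg_sites(g0$genome)), 0L)
})

test_that("generated gene models and islands are internally consistent", {
  g <- simulate_genome(n_chrom = 1, chrom_length = 80000,
                       gene_density = 1 / 10000, cgi_density = 1 / 10000,
                       seed = 29)
  gm <- g$gene_models
  expect_gt(length(gm$transcripts), 0L)
  # exons and UTRs lie inside their transcript
  for (part in c("exons", "utr5", "utr3")) {
    ov <- IRanges::overlapsAny(gm[[part]], gm$transcripts,
                               type = "within", ignore.strand = TRUE)
    expect_true(all(ov))
  }
  # islands disjoint
  expect_equal(length(GenomicRanges::reduce(g$cgi)), length(g$cgi))
})

test_that("planted-null counts give approximately uniform paired-t p-values", {
  des <- sim_design(seed = 601, n_sites = 10000)
  smp <- simulate_site_positions(10000, seed = 601)
  sim <- simulate_counts(smp, des,
                         sim_effects(global_shift = 0, frac_affected = 0))
  lc <- log_cpm(sim$counts$counts, sim$counts$library_sizes)
  sheet <- des$sample_sheet
  pairs <- data.frame(
    sample_A = sheet$sample[sheet$cell_type == "iPSC"],
    sample_B = sheet$sample[sheet$cell_type == "NSC"])
  res <- paired_t(lc, pairs)
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("a planted global shift is recovered by the observed fold changes", {
  des <- sim_design(seed = 602, n_sites = 5000)
  smp <- simulate_site_positions(5000, seed = 602)
  sim <- simulate_counts(smp, des,
                         sim_effects(global_shift = -0.3,
                                     frac_affected = 0,
                                     dispersion = 0.05))
  norm <- normalize_pipeline(sim$counts, des$sample_sheet)
  diff <- differential_sites(norm$logcpm, norm$sample_sheet,
                             c("NSC", "iPSC"))
  expect_lt(abs(mean(diff$log2_fc) - (-0.3)), 0.05)
})

test_that("planted DhMR member sites all show negative fold changes", {
  des <- sim_design(seed = 603, n_sites = 2000)
  smp <- simulate_site_positions(2000, n_chrom = 2, seed = 603)
  pd <- data.frame(chrom = "chr2", start_index = 50L, k = 9L, effect = -2)
  sim <- simulate_counts(smp, des,
                         sim_effects(global_shift = 0, frac_affected = 0,
                                     planted_dhmrs = pd,
                                     dispersion = 0.05))
  norm <- normalize_pipeline(sim$counts, des$sample_sheet)
  diff <- differential_sites(norm$logcpm, norm$sample_sheet,
                             c("NSC", "iPSC"))
  member <- sim$truth$site[!is.na(sim$truth$dhmr_id)]
  fc <- diff$log2_fc[match(member, diff$site)]
  expect_equal(length(fc), 9L)
  expect_true(all(fc < 0))
})

test_that("the ground-truth table covers exactly the non-null sites", {
  des <- sim_design(seed = 604, n_sites = 1000)
  smp <- simulate_site_positions(1000, seed = 604)
  pd <- data.frame(chrom = "chr1", start_index = 10L, k = 9L, effect = 1)
  sim <- simulate_counts(smp, des,
                         sim_effects(frac_affected = 0.05,
                                     planted_dhmrs = pd))
  tr <- sim$truth
  expect_equal(nrow(tr), 1000L)
  expect_true(all(tr$log2_effect[!tr$affected] == 0))
  expect_true(all(tr$log2_effect[!is.na(tr$dhmr_id)] == 1))
  expect_gte(sum(tr$affected), 9L)
})

test_that("read simulation respects levels and decoy bookkeeping", {
  g <- simulate_genome(n_chrom = 1, chrom_length = 20000,
                       ccgg_rate = 1 / 400, seed = 31)
  n <- nrow(g$sitemap)
  lv <- matrix(1, n, 1, dimnames = list(NULL, "S1"))
  lv[1, 1] <- 0   # silenced site emits nothing
  rd <- simulate_reads(g$genome, g$sitemap, lv, depth = 10,
                       decoy_frac = 0.2, seed = 5)
  expect_equal(rd$tallies[1, "S1"], 0L)
  total <- nrow(rd$reads$S1)
  expect_equal(unname(rd$n_decoys["S1"]),
               round(0.2 / 0.8 * (total - rd$n_decoys["S1"]))[[1]])
  # every genuine read starts with the protected-site motif
  genuine <- rd$reads$S1[!grepl("decoy", rd$reads$S1$id), ]
  expect_true(all(startsWith(genuine$seq, "CCGG")))
  expect_true(all(nchar(genuine$seq) >= 35))
  expect_error(simulate_reads(g$genome, g$sitemap, lv * 2, seed = 1),
               "levels")
})

test_that("FASTQ written by the generator round-trips through read_fastq", {
  g <- simulate_genome(n_chrom = 1, chrom_length = 15000,
                       ccgg_rate = 1 / 500, seed = 37)
  lv <- matrix(0.8, nrow(g$sitemap), 1, dimnames = list(NULL, "S1"))
  dir <- tempfile()
  rd <- simulate_reads(g$genome, g$sitemap, lv, depth = 5, seed = 2,
                       dir = dir)
  back <- read_fastq(rd$paths[["S1"]])
  expect_equal(back$seq, rd$reads$S1$seq)
  expect_equal(back$id, rd$reads$S1$id)
})
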