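make_read <- function(seq, id = "r1", qual = strrep("I", nchar(seq))) {
  data.frame(id = id, seq = seq, qual = qual, stringsAsFactors = FALSE)
}

test_that("filter_and_trim keeps, trims and drops by the stated rules", {
  # boundary: exactly 35 nt after the motif check, no trailing CG
  r35 <- make_read(paste0("CCGG", strrep("A", 30), "T"))
  ft <- filter_and_trim(r35)
  expect_equal(ft$report$kept, 1L)
  expect_equal(nchar(ft$kept$seq), 35L)
  # wrong 5' signature
  ft2 <- filter_and_trim(make_read(paste0("ACGG", strrep("A", 40))))
  expect_equal(ft2$report$kept, 0L)
  expect_equal(ft2$report$dropped_no_p5_motif, 1L)
  # 36 nt ending CG -> trimmed to 34 -> too short
  ft3 <- filter_and_trim(make_read(paste0("CCGG", strrep("A", 30), "CG")))
  expect_equal(ft3$report$dropped_too_short, 1L)
  # low-quality 3' tail is trimmed at the Phred floor
  seq <- paste0("CCGG", strrep("A", 40))
  qual <- paste0(strrep("I", 38), strrep("#", 6))  # Q40 x38 then Q2 x6
  ft4 <- filter_and_trim(make_read(seq, qual = qual))
  expect_equal(nchar(ft4$kept$seq), 38L)
})

test_that("kept + dropped equals total for any FASTQ input", {
  set.seed(11)
  seqs <- vapply(1:50, function(i) {
    pre <- sample(c("CCGG", "ACGG", "CCGA"), 1)
    paste0(pre, paste(sample(c("A", "C", "G", "T"),
                             sample(20:60, 1), replace = TRUE),
                      collapse = ""))
  }, character(1))
  reads <- data.frame(id = paste0("r", 1:50), seq = seqs,
                      qual = strrep("I", nchar(seqs)),
                      stringsAsFactors = FALSE)
  rep <- filter_and_trim(reads)$report
  expect_equal(rep$kept + rep$dropped_no_p5_motif + rep$dropped_too_short,
               rep$total)
})

test_that("malformed records are rejected with their index", {
  bad <- data.frame(id = c("a", "b"), seq = c("CCGGAA", "CCGG"),
                    qual = c("IIIIII", "III"), stringsAsFactors = FALSE)
  expect_error(filter_and_trim(bad), "index 2")
})

test_that("place_reads assigns exact matches in both orientations only", {
  toy <- make_toy_genome()
  sm <- find_ccgg_sites(toy$genome)
  s <- toy$genome[["chr1"]]
  fwd <- substring(s, 41, 80)                   # forward read from site 41
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substring(s, 49, 88))))  # reverse read, site 85
  mism <- fwd
  substr(mism, 20, 20) <- if (substr(mism, 20, 20) == "A") "C" else "A"
  reads <- data.frame(id = c("f", "r", "m"), seq = c(fwd, rev, mism),
                      qual = strrep("I", 40), stringsAsFactors = FALSE)
  pl <- place_reads(reads, sm, toy$genome)
  expect_equal(pl$assignments, c("chr1:41", "chr1:85", NA))
  expect_equal(pl$report$assigned, 2L)
  # read order invariance
  pl2 <- place_reads(reads[c(3, 1, 2), ], sm, toy$genome)
  expect_equal(sort(pl2$assignments), sort(pl$assignments))
})

test_that("sitemap/genome mismatch raises a consistency error", {
  toy <- make_toy_genome()
  bad_sm <- toy_sitemap(c(41L, 100L))  # 100 is not a motif start
  expect_error(place_reads(make_read(strrep("A", 40)), bad_sm,
                           toy$genome),
               "mismatch")
})

test_that("count_sites tabulates per sample and keeps zero-count sites", {
  sm <- toy_sitemap(c(41L, 85L, 149L))
  a <- list(S1 = c("chr1:41", "chr1:41", "chr1:41"),
            S2 = c("chr1:85", NA))
  sc <- count_sites(a, sm)
  expect_equal(unname(sc$counts[, "S1"]), c(3L, 0L, 0L))
  expect_equal(unname(sc$counts[, "S2"]), c(0L, 1L, 0L))
  expect_equal(unname(sc$library_sizes), c(3L, 1L))
  expect_error(count_sites(setNames(a, c("S1", "S1")), sm), "unique")
})

test_that("pipeline recovers simulator tallies exactly and drops decoys", {
  g <- simulate_genome(n_chrom = 1, chrom_length = 30000,
                       ccgg_rate = 1 / 500, seed = 21)
  sm <- g$sitemap
  lv <- matrix(runif(nrow(sm) * 2, 0.3, 1), ncol = 2,
               dimnames = list(NULL, c("S1", "S2")))
  rd <- simulate_reads(g$genome, sm, lv, depth = 6, decoy_frac = 0.25,
                       seed = 8)
  for (smp in c("S1", "S2")) {
    ft <- filter_and_trim(rd$reads[[smp]])
    expect_equal(ft$report$dropped_no_p5_motif,
                 unname(rd$n_decoys[smp]))
    pl <- place_reads(ft$kept, sm, g$genome)
    sc <- count_sites(setNames(list(pl$assignments), smp), sm)
    expect_equal(unname(sc$counts[, smp]), unname(rd$tallies[, smp]))
  }
})

write_toy_sam <- function(path, records, chroms = c(chr1 = 300L)) {
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), chroms))
  writeLines(c(hdr, records), path)
}

sam_rec <- function(qname, flag, rname, pos, len = 20L) {
  paste(qname, flag, rname, pos, 60, paste0(len, "M"), "*", 0, 0,
        strrep("A", len), strrep("I", len), sep = "\t")
}

test_that("import_alignments counts records whose motif start hits a site", {
  sm <- toy_sitemap(c(41L, 85L, 149L))
  sam <- tempfile(fileext = ".sam")
  recs <- c(
    sam_rec("f1", 0, "chr1", 41),    # forward on site
    sam_rec("f2", 0, "chr1", 41),
    sam_rec("f3", 0, "chr1", 85),
    sam_rec("f4", 0, "chr1", 149),
    sam_rec("r1", 16, "chr1", 41 - 16),   # reverse: motif start 41
    sam_rec("r2", 16, "chr1", 85 - 16),   # reverse: motif start 85
    sam_rec("r3", 16, "chr1", 149 - 16),  # reverse: motif start 149
    sam_rec("x1", 0, "chr1", 10),    # off-site
    sam_rec("x2", 0, "chr1", 200),   # off-site
    sam_rec("x3", 16, "chr1", 60))   # reverse off-site (motif start 76)
  write_toy_sam(sam, recs)
  sc <- import_alignments(c(S1 = sam), sm, format = "sam")
  expect_equal(unname(sc$library_sizes), 7L)
  expect_equal(unname(sc$counts[, "S1"]), c(3L, 2L, 2L))
})

test_that("unknown chromosomes are skipped with a warning", {
  sm <- toy_sitemap(41L)
  sam <- tempfile(fileext = ".sam")
  write_toy_sam(sam, c(sam_rec("a", 0, "chr1", 41),
                       sam_rec("b", 0, "chrZ", 41)),
                chroms = c(chr1 = 300L, chrZ = 300L))
  expect_warning(sc <- import_alignments(c(S1 = sam), sm, "sam"),
                 "chrZ")
  expect_equal(unname(sc$library_sizes), 1L)
})
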