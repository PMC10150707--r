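# Shared fixtures, all built in code.

# Tiny single-chromosome genome with three known CCGG sites at 41, 85
# and 149, embedded in distinct random filler (so every site context is
# unique and exact placement is unambiguous). The seed search makes the
# construction deterministic and guaranteed free of accidental motifs.
make_toy_genome <- function() {
  target <- c(41L, 85L, 149L)
  seed <- 0L
  repeat {
    seed <- seed + 1L
    set.seed(seed)
    parts <- vapply(c(40L, 40L, 60L, 40L), function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
            collapse = ""), character(1))
    s <- paste0(parts[1], "CCGG", parts[2], "CCGG", parts[3], "CCGG",
                parts[4])
    hits <- as.integer(gregexpr("CCGG", s, fixed = TRUE)[[1]])
    if (identical(hits, target)) break
  }
  list(genome = c(chr1 = s), sites = target)
}

# Hand-built gene models on chr1: forward gene A (2000-5999) with
# 5'UTR 2000-2199, exon 2200-2699, intron 2700-5399, exon 5400-5699,
# 3'UTR 5700-5999; reverse gene B (9000-11999) with TSS at 11999.
make_toy_gene_models <- function() {
  gr <- function(start, end, strand, gene) {
    g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start, end),
                                strand = strand)
    g$gene_id <- gene
    g$transcript_id <- paste0(gene, ".1")
    g
  }
  tx <- c(gr(2000, 5999, "+", "GENEA"), gr(9000, 11999, "-", "GENEB"))
  exons <- c(gr(2000, 2699, "+", "GENEA"), gr(5400, 5999, "+", "GENEA"),
             gr(9000, 11999, "-", "GENEB"))
  utr5 <- c(gr(2000, 2199, "+", "GENEA"), gr(11800, 11999, "-", "GENEB"))
  utr3 <- c(gr(5700, 5999, "+", "GENEA"), gr(9000, 9199, "-", "GENEB"))
  tss <- GenomicRanges::resize(tx, width = 1L, fix = "start")
  list(transcripts = tx, exons = exons, utr5 = utr5, utr3 = utr3,
       tss = tss)
}

# Site map at given positions on one chromosome.
toy_sitemap <- function(pos, chrom = "chr1") {
  structure(data.frame(chrom = chrom, pos = as.integer(pos),
                       stringsAsFactors = FALSE),
            genome_id = "toy", class = c("site_map", "data.frame"))
}

# Gaussian null log2-CPM matrix with chrom:pos row keys.
make_null_logcpm <- function(n_sites, n_samples = 8, seed = 1,
                             spacing = 100) {
  set.seed(seed)
  matrix(rnorm(n_sites * n_samples), n_sites, n_samples,
         dimnames = list(paste0("chr1:",
                                seq(1, by = spacing,
                                    length.out = n_sites)),
                         paste0("S", seq_len(n_samples))))
}

toy_pairs <- function(n = 4) {
  data.frame(sample_A = paste0("S", seq_len(n)),
             sample_B = paste0("S", n + seq_len(n)))
}
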